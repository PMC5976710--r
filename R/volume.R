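## Volume data model ---------------------------------------------------------
##
## A `volume` is a 3D scalar grid embedded in world space (LPS millimetres,
## the DICOM/ITK convention). Voxel indices are 0-based in the geometry
## formulas and a voxel's world point is its centre:
##
##   world(i) = origin + direction %*% (spacing * i)
##
## `direction` is a 3x3 orthonormal matrix (|det| = 1).

#' Construct a volume
#'
#' A volume couples a 3D scalar array (HU-like intensities) with its world
#' geometry: voxel spacing in mm, the world position of voxel `(0,0,0)`
#' (0-based), and an orthonormal direction matrix. World coordinates are LPS
#' millimetres and a voxel's world point is its centre.
#'
#' @param data 3D numeric array, at least 2 voxels per axis.
#' @param spacing Numeric 3-vector, mm per voxel, strictly positive.
#' @param origin Numeric 3-vector, mm.
#' @param direction 3x3 orthonormal matrix.
#' @return An object of class `volume`.
#' @examples
#' v <- volume(array(0, c(8, 8, 8)), spacing = c(0.68, 0.68, 2.5))
#' dim(v$data)
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   direction = diag(3)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("non-3D payload: 'data' must be a 3D array")
  if (any(dim(data) < 2L))
    stop("non-3D payload: every axis needs >= 2 voxels")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be a finite 3-vector (mm)")
  direction <- matrix(as.numeric(direction), 3L, 3L)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("direction must be orthonormal")
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, origin = origin,
                 direction = direction),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat("<volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  cat("  origin (mm): ", paste(signif(x$origin, 6), collapse = ", "), "\n",
      sep = "")
  cat("  intensity range: ", paste(signif(range(x$data), 6), collapse = " .. "),
      "\n", sep = "")
  invisible(x)
}

is_volume <- function(x) inherits(x, "volume")

stopifnot_volume <- function(v, what = "volume") {
  if (!is_volume(v)) stop("expected a '", what, "' object")
  invisible(v)
}

#' Grid specification
#'
#' The geometry of a volume without its intensities: target grid for
#' resampling and warping.
#'
#' @param shape Integer 3-vector of voxel counts.
#' @param spacing,origin,direction As in [volume()].
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      direction = diag(3)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 2L))
    stop("shape must be 3 integers >= 2")
  g <- volume(array(0, c(2, 2, 2)), spacing, origin, direction) # validate geometry
  structure(list(shape = shape, spacing = g$spacing, origin = g$origin,
                 direction = g$direction),
            class = "grid_spec")
}

#' Grid of an existing volume
#' @param v A `volume`.
#' @return The `grid_spec` carrying `v`'s geometry.
#' @export
grid_of <- function(v) {
  stopifnot_volume(v)
  grid_spec(dim(v$data), v$spacing, v$origin, v$direction)
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("<grid_spec> ", paste(x$shape, collapse = " x "), " voxels @ ",
      paste(signif(x$spacing, 4), collapse = " x "), " mm\n", sep = "")
  invisible(x)
}

## 3x4 matrix mapping 0-based voxel index -> world mm
index_to_world_matrix <- function(g) {
  cbind(g$direction %*% diag(g$spacing), g$origin)
}

## 3x4 matrix mapping world mm -> 0-based continuous voxel index
world_to_index_matrix <- function(g) {
  A <- diag(1 / g$spacing) %*% t(g$direction)
  cbind(A, -A %*% g$origin)
}

#' Convert voxel indices to world coordinates
#'
#' @param g A `volume` or `grid_spec`.
#' @param idx n x 3 matrix of 0-based voxel indices (may be fractional).
#' @return n x 3 matrix of world points (mm, LPS).
#' @export
index_to_world <- function(g, idx) {
  idx <- rbind(idx)
  M <- index_to_world_matrix(g)
  t(M %*% rbind(t(idx), 1))
}

#' Convert world coordinates to (continuous) voxel indices
#' @inheritParams index_to_world
#' @param pts n x 3 matrix of world points (mm).
#' @return n x 3 matrix of 0-based continuous indices.
#' @export
world_to_index <- function(g, pts) {
  pts <- rbind(pts)
  M <- world_to_index_matrix(g)
  t(M %*% rbind(t(pts), 1))
}

#' Clamp intensities to a window
#'
#' Clips intensities into `[lo, hi]` (e.g. a soft-tissue HU window before
#' histogram-based similarity metrics); geometry is unchanged.
#'
#' @param v A `volume`.
#' @param lo,hi Window bounds, `lo < hi`.
#' @return A `volume`.
#' @export
clamp_window <- function(v, lo, hi) {
  stopifnot_volume(v)
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop("ill-posed window: need lo < hi")
  v$data[] <- pmin(pmax(v$data, lo), hi)
  v
}

interp_code <- function(interp) {
  switch(match.arg(interp, c("nearest", "linear", "bspline3")),
         nearest = 0L, linear = 1L, bspline3 = 3L)
}

#' Resample a volume onto a target grid
#'
#' Each output voxel takes the interpolated value of `moving` at the output
#' voxel's world point. World points outside the extent of `moving` receive
#' `fill` (default: the minimum of `moving`, approximating CT background).
#'
#' @param moving A `volume`.
#' @param grid A `grid_spec` (or `volume`, whose geometry is used).
#' @param interp One of `"nearest"`, `"linear"`, `"bspline3"`. Cubic B-spline
#'   interpolation uses exact prefiltered coefficients, so it interpolates
#'   (reproduces samples), not merely smooths.
#' @param fill Out-of-extent fill value.
#' @return A `volume` on `grid`.
#' @export
resample_to_grid <- function(moving, grid, interp = "linear",
                             fill = min(moving$data)) {
  stopifnot_volume(moving)
  if (is_volume(grid)) grid <- grid_of(grid)
  if (!inherits(grid, "grid_spec")) stop("'grid' must be a grid_spec")
  warp(moving, transform_chain(), grid, interp = interp, fill = fill)
}

## Interpolate a volume at world points (used by tests and the phantom).
interp_at_world <- function(v, pts, interp = "linear", fill = min(v$data)) {
  idx <- world_to_index(v, pts)
  cpp_interp_points(v$data, idx, interp_code(interp), fill)
}
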