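## Spatial transforms --------------------------------------------------------
##
## CONVENTION (important): every transform maps FIXED-space world points to
## MOVING-space world points (the resampling / pull-back convention). The
## intraprocedural CBCT is the fixed (template) image and the pre-ablation
## CECT the moving image, so warping paints CECT content onto the CBCT grid.
## A `transform_chain` is an ordered list; application order is list order
## (the first element is applied to the fixed-space point first). The
## registration pipeline therefore *prepends* each newly estimated stage, so
## the nonrigid stage acts directly on fixed-space points and its control
## grid covers the fixed-image domain.

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3x3 rotation matrix (orthonormal, det = +1).
#' @param translation 3-vector, mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 || det(rotation) < 0)
    stop("rotation must be orthonormal with det = +1")
  if (length(translation) != 3L) stop("translation must be a 3-vector")
  structure(list(rotation = rotation, translation = translation),
            class = c("rigid_transform", "ablation_transform"))
}

#' Affine transform with a centre
#'
#' Maps `x` to `matrix %*% (x - center) + center + translation`.
#'
#' @param matrix Invertible 3x3 matrix.
#' @param translation 3-vector, mm.
#' @param center Fixed point of the linear part, mm.
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(matrix = diag(3), translation = c(0, 0, 0),
                             center = c(0, 0, 0)) {
  matrix <- base::matrix(as.numeric(matrix), 3, 3)
  if (abs(det(matrix)) <= 1e-12) stop("affine matrix is singular")
  structure(list(matrix = matrix, translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = c("affine_transform", "ablation_transform"))
}

#' Cubic B-spline free-form deformation
#'
#' Displacement field `d(x)` parameterised by displacements of a regular,
#' axis-aligned control-point lattice; the transform maps `x` to `x + d(x)`.
#' The lattice must cover the fixed-image domain plus the cubic support
#' margin (one extra control point beyond each face).
#'
#' @param origin World position (mm) of control point `(0,0,0)`.
#' @param spacing Control-point spacing, mm (3-vector or scalar).
#' @param shape Integer 3-vector of control-point counts (>= 4 per axis).
#' @param coefficients 4D array `c(shape, 3)` of control-point displacements
#'   in mm; defaults to zeros (identity).
#' @return An object of class `bspline_transform`.
#' @export
bspline_transform <- function(origin, spacing, shape, coefficients = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 4L))
    stop("control grid needs >= 4 points per axis")
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  if (any(spacing <= 0)) stop("control spacing must be positive")
  if (is.null(coefficients)) coefficients <- array(0, c(shape, 3L))
  if (!identical(dim(coefficients), c(shape, 3L)))
    stop("coefficients must have dim c(shape, 3)")
  storage.mode(coefficients) <- "double"
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 shape = shape, coefficients = coefficients),
            class = c("bspline_transform", "ablation_transform"))
}

#' Ordered chain of transforms
#'
#' Maps fixed-space world points to moving-space world points by applying its
#' elements in list order. An empty chain is the identity.
#'
#' @param ... Transforms (`rigid_transform`, `affine_transform`,
#'   `bspline_transform`) or a single list of them.
#' @return An object of class `transform_chain`.
#' @export
transform_chain <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) &&
      !inherits(xs[[1]], "ablation_transform"))
    xs <- xs[[1]]
  ok <- vapply(xs, inherits, logical(1), what = "ablation_transform")
  if (!all(ok)) stop("chain elements must be transforms")
  structure(xs, class = "transform_chain")
}

#' @export
print.transform_chain <- function(x, ...) {
  cat("<transform_chain> fixed -> moving,", length(x), "stage(s):",
      if (length(x)) paste(vapply(x, function(t) class(t)[1], ""),
                           collapse = " -> ") else "identity", "\n")
  invisible(x)
}

as_chain <- function(x) {
  if (inherits(x, "transform_chain")) return(x)
  if (inherits(x, "ablation_transform")) return(transform_chain(list(x)))
  if (is.null(x)) return(transform_chain())
  stop("expected a transform or transform_chain")
}

## 3x4 homogeneous form of an affine-like transform
affine_as_matrix <- function(t) {
  if (inherits(t, "rigid_transform"))
    cbind(t$rotation, t$translation)
  else if (inherits(t, "affine_transform"))
    cbind(t$matrix, t$center + t$translation - t$matrix %*% t$center)
  else stop("not an affine-like transform")
}

## Low-level chain description consumed by the C++ kernels.
chain_spec <- function(chain) {
  chain <- as_chain(chain)
  lapply(unclass(chain), function(t) {
    if (inherits(t, "bspline_transform"))
      list(type = 1L, origin = t$origin, spacing = t$spacing,
           dims = t$shape, coef = t$coefficients)
    else
      list(type = 0L, M = affine_as_matrix(t))
  })
}

#' Apply a transform or chain to world points
#'
#' @param transform A transform or `transform_chain` (fixed -> moving).
#' @param pts n x 3 matrix of fixed-space world points (mm).
#' @return n x 3 matrix of moving-space world points.
#' @export
apply_transform <- function(transform, pts) {
  pts <- rbind(pts)
  storage.mode(pts) <- "double"
  cpp_apply_chain(chain_spec(as_chain(transform)), pts)
}

## Numerically invert a chain at given moving-space points: find fixed-space
## p with chain(p) = y. Affine parts are inverted in closed form; B-spline
## displacements by fixed-point iteration (valid for the smooth, moderate
## fields used here where the displacement Jacobian norm is < 1).
invert_chain_points <- function(chain, pts, tol = 1e-12, max_iter = 200) {
  chain <- as_chain(chain)
  y <- rbind(pts)
  for (t in rev(unclass(chain))) {
    if (inherits(t, "bspline_transform")) {
      spec <- chain_spec(transform_chain(list(t)))
      x <- y
      for (k in seq_len(max_iter)) {
        d <- cpp_apply_chain(spec, x) - x   # displacement at current x
        x_new <- y - d
        if (max(abs(x_new - x)) < tol) { x <- x_new; break }
        x <- x_new
      }
      y <- x
    } else {
      M <- affine_as_matrix(t)
      A <- M[, 1:3]; b <- M[, 4]
      y <- t(solve(A, t(y) - b))
    }
  }
  y
}

transform_to_list <- function(t) {
  if (inherits(t, "rigid_transform"))
    list(type = "rigid", rotation = t$rotation, translation = t$translation)
  else if (inherits(t, "affine_transform"))
    list(type = "affine", matrix = t$matrix, translation = t$translation,
         center = t$center)
  else
    list(type = "bspline", origin = t$origin, spacing = t$spacing,
         shape = t$shape, coefficients = as.numeric(t$coefficients))
}

transform_from_list <- function(l) {
  switch(l$type,
    rigid = rigid_transform(matrix(unlist(l$rotation), 3, 3, byrow = TRUE),
                            unlist(l$translation)),
    affine = affine_transform(matrix(unlist(l$matrix), 3, 3, byrow = TRUE),
                              unlist(l$translation), unlist(l$center)),
    bspline = {
      shape <- as.integer(unlist(l$shape))
      bspline_transform(unlist(l$origin), unlist(l$spacing), shape,
                        array(unlist(l$coefficients), c(shape, 3L)))
    },
    stop("unknown transform type: ", l$type))
}

#' Serialize a transform chain to JSON
#'
#' The file records the resampling convention (`fixed_to_moving`) alongside
#' the stages so downstream consumers cannot misread the direction.
#'
#' @param chain A `transform_chain` or single transform.
#' @param path Output JSON path.
#' @export
write_transform_chain <- function(chain, path) {
  chain <- as_chain(chain)
  obj <- list(convention = "fixed_to_moving",
              transforms = lapply(unclass(chain), transform_to_list))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a transform chain from JSON
#' @param path JSON path written by [write_transform_chain()].
#' @return A `transform_chain`.
#' @export
read_transform_chain <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$convention, "fixed_to_moving"))
    stop("transform file lacks the fixed_to_moving convention tag")
  transform_chain(lapply(obj$transforms, transform_from_list))
}
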