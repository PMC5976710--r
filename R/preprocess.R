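## Denoising and segmentation stack ------------------------------------------
##
## Liver: fast marching grows an initial region from user seeds, a geodesic
## active contour refines it against an edge-stopping feature map.
## Tumor / ablation zone: fuzzy c-means over ROI densities synthesises
## high-confidence seeds, a random walker solves the seeded labelling.

#' Perona-Malik anisotropic diffusion denoising
#'
#' Explicit scheme over the six face neighbours with conductance
#' `exp(-(|grad I| / kappa)^2)` on one-sided differences (voxel units) and
#' zero-flux (Neumann) boundaries. Edges steeper than `kappa` are preserved
#' while flatter noise diffuses away.
#'
#' @param v A [volume()].
#' @param iterations Number of explicit steps (>= 0).
#' @param kappa Conductance scale, intensity units (HU), > 0.
#' @param dt Step size; stability requires `dt <= 1/(2 * ndim) = 1/6`.
#' @return The filtered `volume` (geometry unchanged).
#' @export
diffusion_filter <- function(v, iterations = 5, kappa = 20, dt = 1/6) {
  stopifnot_volume(v)
  if (iterations < 0) stop("iterations must be >= 0")
  if (!(dt > 0 && dt <= 1 / 6))
    stop("dt outside stability bound (0, 1/(2*ndim)] = (0, 1/6]")
  if (kappa <= 0) stop("kappa must be > 0")
  if (iterations == 0) return(v)
  v$data <- cpp_diffusion(v$data, as.integer(iterations), kappa, dt)
  v
}

#' Fast marching arrival times
#'
#' Solves the Eikonal equation `|grad T| * speed = 1` with `T = 0` at the
#' seed voxels (first-order upwind fast-marching method, anisotropic
#' spacing). Arrival times are in the units of `1/speed * mm`.
#'
#' Multi-seed arrivals are computed as the voxelwise minimum over
#' single-seed solutions, so the first-arrival (min) property holds exactly
#' and the result is independent of seed order.
#'
#' @param speed A `volume` of strictly positive front speeds.
#' @param seeds n x 3 matrix of 1-based voxel indices (at least one).
#' @return A `volume` of arrival times.
#' @export
fast_marching <- function(speed, seeds) {
  stopifnot_volume(speed)
  if (any(speed$data <= 0)) stop("speed must be strictly positive")
  seeds <- rbind(seeds)
  if (nrow(seeds) < 1L) stop("at least one seed is required")
  d <- dim(speed$data)
  if (any(seeds < 1L) || any(t(seeds) > d))
    stop("seed out of bounds")
  storage.mode(seeds) <- "integer"
  out <- NULL
  for (i in seq_len(nrow(seeds))) {
    ti <- cpp_fast_marching(speed$data, speed$spacing,
                            seeds[i, , drop = FALSE] - 1L)
    out <- if (is.null(out)) ti else pmin(out, ti)
  }
  speed$data <- out
  speed
}

#' Edge-stopping feature map
#'
#' Sigmoid of the gradient magnitude: close to 1 in homogeneous tissue,
#' close to 0 on strong edges; input for [geodesic_active_contour()] and a
#' usable fast-marching speed.
#'
#' @param v A `volume` (denoise first).
#' @param alpha Sigmoid width (HU/mm); larger = softer transition.
#' @param beta Gradient magnitude (HU/mm) mapped to 0.5.
#' @return A `volume` with values in (0, 1).
#' @export
edge_feature <- function(v, alpha = 10, beta = 40) {
  stopifnot_volume(v)
  g <- gradient_magnitude(v$data, v$spacing)
  v$data <- 1 / (1 + exp((g - beta) / alpha))
  v
}

gradient_magnitude <- function(a, spacing) {
  d <- dim(a)
  gx <- array(0, d); gy <- array(0, d); gz <- array(0, d)
  gx[2:(d[1] - 1), , ] <- (a[3:d[1], , ] - a[1:(d[1] - 2), , ]) /
    (2 * spacing[1])
  gy[, 2:(d[2] - 1), ] <- (a[, 3:d[2], ] - a[, 1:(d[2] - 2), ]) /
    (2 * spacing[2])
  gz[, , 2:(d[3] - 1)] <- (a[, , 3:d[3]] - a[, , 1:(d[3] - 2)]) /
    (2 * spacing[3])
  sqrt(gx^2 + gy^2 + gz^2)
}

central_gradients <- function(a, spacing) {
  d <- dim(a)
  gx <- array(0, d); gy <- array(0, d); gz <- array(0, d)
  gx[2:(d[1] - 1), , ] <- (a[3:d[1], , ] - a[1:(d[1] - 2), , ]) /
    (2 * spacing[1])
  gy[, 2:(d[2] - 1), ] <- (a[, 3:d[2], ] - a[, 1:(d[2] - 2), ]) /
    (2 * spacing[2])
  gz[, , 2:(d[3] - 1)] <- (a[, , 3:d[3]] - a[, , 1:(d[3] - 2)]) /
    (2 * spacing[3])
  list(gx, gy, gz)
}

## signed distance (mm) to a mask boundary, negative inside
signed_distance <- function(mask_arr, spacing) {
  inside <- mask_arr > 0
  d_to_fg <- sqrt(cpp_edt_sq(inside, spacing))
  d_to_bg <- sqrt(cpp_edt_sq(!inside, spacing))
  d_to_fg - d_to_bg
}

#' Geodesic active contour segmentation
#'
#' Level-set evolution of an initial region under propagation (balloon),
#' curvature and edge-attraction (advection) forces on an edge-stopping
#' feature map in `[0, 1]` (see [edge_feature()]). The level set is
#' maintained as a signed distance (reinitialised periodically) and evolution
#' stops at the iteration budget or once the RMS level-set change per step
#' falls below `tol`.
#'
#' @param feature A `volume` with values in `[0, 1]`.
#' @param init Initial mask (`volume` with 0/1 data), non-empty.
#' @param propagation,curvature,advection Force weights.
#' @param iterations Iteration budget.
#' @param dt Explicit time step.
#' @param tol RMS convergence tolerance.
#' @param reinit_every Reinitialise the signed distance every this many steps.
#' @param band Narrow-band half width (mm): only voxels with `|phi| <= band`
#'   evolve between reinitialisations, which keeps the front from leaking
#'   across thin low-speed shells.
#' @return A mask `volume` (1 inside the final contour).
#' @export
geodesic_active_contour <- function(feature, init, propagation = 1,
                                    curvature = 0.2, advection = 1,
                                    iterations = 200, dt = 0.5, tol = 1e-4,
                                    reinit_every = 10,
                                    band = 2 * max(feature$spacing)) {
  stopifnot_volume(feature); stopifnot_volume(init)
  if (min(feature$data) < -1e-9 || max(feature$data) > 1 + 1e-9)
    stop("feature map must lie in [0, 1]")
  if (sum(init$data > 0) == 0) stop("empty init mask")
  g <- feature$data
  gr <- central_gradients(g, feature$spacing)
  phi <- signed_distance(init$data, feature$spacing)
  done <- 0L
  while (done < iterations) {
    todo <- min(reinit_every, iterations - done)
    res <- cpp_gac_evolve(phi, g, gr[[1]], gr[[2]], gr[[3]], feature$spacing,
                          propagation, curvature, advection,
                          as.integer(todo), dt, tol, band)
    phi <- res$phi
    done <- done + res$iterations
    if (res$rms_change < tol) break
    phi <- signed_distance(phi < 0, feature$spacing)
  }
  feature$data <- array(as.double(phi < 0), dim(phi))
  feature
}

#' Semiautomatic liver segmentation
#'
#' Fast marching from user-supplied seed voxels on the edge-stopping feature
#' map grows an initial region (arrival time below `time_threshold`), which a
#' geodesic active contour then refines.
#'
#' @param v A `volume` (arterial-phase CT; denoise first for noisy data).
#' @param seeds n x 3 matrix of 1-based voxel indices inside the liver.
#' @param alpha,beta Passed to [edge_feature()].
#' @param time_threshold Fast-marching arrival time defining the initial
#'   region (same units as [fast_marching()] output).
#' @param ... Passed to [geodesic_active_contour()].
#' @return A mask `volume`.
#' @export
segment_liver <- function(v, seeds, alpha = 10, beta = 40,
                          time_threshold = 30, ...) {
  feat <- edge_feature(v, alpha, beta)
  tt <- fast_marching(feat, seeds)
  init <- feat
  init$data <- array(as.double(tt$data <= time_threshold), dim(tt$data))
  if (sum(init$data) == 0) stop("fast-marching front never reached threshold")
  geodesic_active_contour(feat, init, ...)
}

#' Fuzzy c-means clustering of scalar intensities
#'
#' Standard FCM alternating updates on 1D values. Centroids are initialised
#' at evenly spaced quantiles, making the fit deterministic; `seed` is
#' accepted for interface uniformity with the stochastic stages.
#'
#' @param values Numeric vector.
#' @param c Number of classes (>= 2).
#' @param m Fuzzifier (> 1).
#' @param tol Convergence threshold on centroid movement.
#' @param max_iter Iteration cap.
#' @param seed Unused (deterministic initialisation); kept for API symmetry.
#' @return An object of class `fcm_result`: `centroids` (increasing) and
#'   `memberships` (n x c, rows sum to 1).
#' @export
fuzzy_cmeans <- function(values, c = 3, m = 2, tol = 1e-6, max_iter = 200,
                         seed = 0) {
  values <- as.numeric(values)
  if (c < 2) stop("c must be >= 2")
  if (m <= 1) stop("fuzzifier m must be > 1")
  if (length(unique(values)) < c)
    stop("degenerate input: fewer distinct values (",
         length(unique(values)), ") than classes (", c, ")")
  cen <- as.numeric(quantile(values, probs = (seq_len(c) - 0.5) / c,
                             type = 7))
  # collapse accidental ties in the quantile initialisation
  if (any(diff(cen) <= 0))
    cen <- seq(min(values), max(values), length.out = c)
  n <- length(values)
  expo <- 2 / (m - 1)
  u <- matrix(0, n, c)
  for (it in seq_len(max_iter)) {
    d2 <- abs(outer(values, cen, "-"))
    zero <- d2 < 1e-300
    u[] <- 0
    anyzero <- rowSums(zero) > 0
    if (any(anyzero)) u[anyzero, ] <- zero[anyzero, ] / rowSums(zero)[anyzero]
    if (any(!anyzero)) {
      r <- d2[!anyzero, , drop = FALSE]^(-expo)
      u[!anyzero, ] <- r / rowSums(r)
    }
    um <- u^m
    new_cen <- colSums(um * values) / colSums(um)
    moved <- max(abs(new_cen - cen))
    cen <- new_cen
    if (moved < tol) break
  }
  ord <- order(cen)
  structure(list(centroids = cen[ord],
                 memberships = u[, ord, drop = FALSE],
                 iterations = it),
            class = "fcm_result")
}

#' @export
print.fcm_result <- function(x, ...) {
  cat("<fcm_result>", length(x$centroids), "classes, centroids:",
      paste(signif(x$centroids, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Random-walker segmentation
#'
#' Solves the combinatorial Dirichlet problem on the 6-connected voxel graph
#' with Gaussian intensity weights `w = exp(-beta * (dI)^2)`: the probability
#' that a random walker released at each voxel first reaches a seed of each
#' label. Seeded voxels keep their label with probability 1.
#'
#' @param v A `volume`.
#' @param seeds Integer array of `dim(v$data)`: 0 = unlabeled, k > 0 = seed
#'   of label k. At least two distinct nonzero labels.
#' @param beta Weight decay per squared intensity difference (> 0).
#' @return 4D array `c(dim(v), n_labels)` of per-label probabilities; the
#'   label values are returned in attribute `labels`.
#' @export
random_walker <- function(v, seeds, beta = 0.005) {
  stopifnot_volume(v)
  if (beta <= 0) stop("beta must be > 0")
  d <- dim(v$data)
  seeds <- array(as.integer(seeds), d)
  labels <- sort(unique(seeds[seeds > 0]))
  if (length(labels) < 2) stop("need seeds of at least 2 distinct labels")
  N <- prod(d)
  idx <- array(seq_len(N), d)
  # 6-connected edges
  e_from <- c(as.vector(idx[-d[1], , ]), as.vector(idx[, -d[2], ]),
              as.vector(idx[, , -d[3]]))
  e_to   <- c(as.vector(idx[-1, , ]),   as.vector(idx[, -1, ]),
              as.vector(idx[, , -1]))
  dI <- v$data[e_from] - v$data[e_to]
  w <- exp(-beta * dI^2) + 1e-10
  L <- Matrix::sparseMatrix(i = c(e_from, e_to), j = c(e_to, e_from),
                            x = -c(w, w), dims = c(N, N))
  Matrix::diag(L) <- -Matrix::rowSums(L)
  seeded <- which(as.vector(seeds) > 0)
  free <- which(as.vector(seeds) == 0)
  probs <- array(0, c(d, length(labels)))
  if (length(free) > 0) {
    LU <- L[free, free, drop = FALSE]
    B <- L[free, seeded, drop = FALSE]
    M <- matrix(0, length(seeded), length(labels))
    for (j in seq_along(labels)) M[, j] <- as.numeric(seeds[seeded] == labels[j])
    X <- as.matrix(Matrix::solve(LU, -B %*% M))
    # clip solver fuzz and renormalise
    X[X < 0] <- 0; X[X > 1] <- 1
    X <- X / rowSums(X)
  }
  for (j in seq_along(labels)) {
    pj <- numeric(N)
    pj[seeded] <- as.numeric(seeds[seeded] == labels[j])
    if (length(free) > 0) pj[free] <- X[, j]
    probs[, , , j] <- pj
  }
  attr(probs, "labels") <- labels
  probs
}

#' Lesion segmentation (tumor or ablation zone)
#'
#' The density-based hybrid pipeline: diffusion denoising, 3-class fuzzy
#' c-means over the ROI intensities (hypodense necrosis / parenchyma /
#' hyperdense enhancing tissue), synthesis of high-confidence seeds from the
#' memberships, random-walker labelling, and retention of the largest
#' connected component. `tumor` mode targets the hyperdense (arterially
#' enhancing) class, `ablation` the hypodense class.
#'
#' @param v A `volume`.
#' @param roi A non-empty mask `volume` delimiting the search region.
#' @param mode `"tumor"` or `"ablation"`.
#' @param config See [lesion_config()].
#' @return A mask `volume` (subset of `roi`).
#' @export
segment_lesion <- function(v, roi, mode = c("tumor", "ablation"),
                           config = lesion_config()) {
  mode <- match.arg(mode)
  stopifnot_volume(v); stopifnot_volume(roi)
  if (!identical(dim(v$data), dim(roi$data)))
    stop("roi grid does not match the volume grid")
  if (sum(roi$data > 0) == 0) stop("empty ROI")
  config <- modifyList(lesion_config(), config)
  # work on the ROI bounding box (plus margin) for tractability
  w <- which(roi$data > 0, arr.ind = TRUE)
  lo <- pmax(apply(w, 2, min) - 2L, 1L)
  hi <- pmin(apply(w, 2, max) + 2L, dim(v$data))
  sub <- v
  sub$data <- v$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sub_roi <- roi$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sub <- diffusion_filter(sub, config$diffusion$iterations,
                          config$diffusion$kappa, config$diffusion$dt)
  inroi <- sub_roi > 0
  fcm <- fuzzy_cmeans(sub$data[inroi], c = config$fcm$c, m = config$fcm$m,
                      tol = config$fcm$tol)
  target <- if (mode == "tumor") config$fcm$c else 1L
  u <- fcm$memberships
  seeds <- array(0L, dim(sub$data))
  tgt_seed <- u[, target] > config$seed_threshold
  other <- apply(u[, -target, drop = FALSE], 1, max) > config$seed_threshold
  sv <- integer(sum(inroi))
  sv[tgt_seed] <- 1L
  sv[other & !tgt_seed] <- 2L
  seeds[inroi] <- sv
  seeds[!inroi] <- 2L   # everything outside the ROI is background
  if (!any(seeds == 1L) || !any(seeds == 2L))
    stop("no seeds produced at membership threshold ", config$seed_threshold)
  probs <- random_walker(sub, seeds, beta = config$rw$beta)
  lab1 <- probs[, , , 1] >= 0.5 & inroi
  cc <- cpp_label_components(lab1)
  if (max(cc) > 0) {
    sizes <- tabulate(cc[cc > 0])
    lab1 <- cc == which.max(sizes)
  }
  out <- roi
  out$data <- array(0, dim(roi$data))
  out$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- as.double(lab1)
  out
}

#' Default lesion-segmentation configuration
#'
#' @return Nested list of defaults: `diffusion` (iterations 5, kappa 20 HU,
#'   dt 1/6), `fcm` (c = 3 density classes, fuzzifier 2, tol 1e-6),
#'   `rw` (beta 0.005 per HU^2), and `seed_threshold` 0.8 (membership above
#'   which a voxel becomes a Dirichlet seed).
#' @export
lesion_config <- function() {
  list(diffusion = list(iterations = 5, kappa = 20, dt = 1 / 6),
       fcm = list(c = 3L, m = 2, tol = 1e-6),
       rw = list(beta = 0.005),
       seed_threshold = 0.8)
}
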