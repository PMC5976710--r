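## Four-step CECT -> CE-CBCT registration ------------------------------------
##
## (1) resample the moving CECT at CBCT resolution, (2) rigid initialisation
## from three paired vessel landmarks, (3) NMI-driven affine then cubic
## B-spline free-form refinement, (4) warping of images/masks onto the CBCT
## grid. The CBCT is fixed, the CECT moving; chains map fixed world points
## to moving world points and each new stage is prepended (see transforms.R),
## so the B-spline lattice lives on the fixed-image domain.

#' Paired registration landmarks
#'
#' @param fixed,moving n x 3 matrices of corresponding world points (mm);
#'   `fixed` in CBCT space, `moving` in CECT space; n >= 3 and the fixed
#'   points must not be collinear.
#' @return An object of class `landmark_pairs`.
#' @export
landmark_pairs <- function(fixed, moving) {
  fixed <- rbind(fixed); moving <- rbind(moving)
  storage.mode(fixed) <- storage.mode(moving) <- "double"
  if (nrow(fixed) != nrow(moving)) stop("unequal numbers of paired points")
  if (nrow(fixed) < 3) stop("at least 3 landmark pairs are required")
  A <- sweep(fixed, 2, colMeans(fixed))
  sv <- svd(A)$d
  if (sv[2] <= 1e-9 * max(sv[1], 1))
    stop("rank error: fixed landmarks are collinear")
  structure(list(fixed = fixed, moving = moving), class = "landmark_pairs")
}

#' @export
print.landmark_pairs <- function(x, ...) {
  cat("<landmark_pairs>", nrow(x$fixed), "pairs (fixed = CBCT space)\n")
  invisible(x)
}

#' Read paired landmarks from CSV
#'
#' Expects the header `fixed_x,fixed_y,fixed_z,moving_x,moving_y,moving_z`
#' (world mm).
#' @param path CSV path.
#' @return A [landmark_pairs()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.csv(path)
  need <- c("fixed_x", "fixed_y", "fixed_z",
            "moving_x", "moving_y", "moving_z")
  if (!all(need %in% names(d)))
    stop("landmark CSV must have columns: ", paste(need, collapse = ","))
  landmark_pairs(as.matrix(d[, need[1:3]]), as.matrix(d[, need[4:6]]))
}

#' Write paired landmarks to CSV
#' @param pairs A [landmark_pairs()].
#' @param path Output CSV path.
#' @export
write_landmarks <- function(pairs, path) {
  d <- data.frame(pairs$fixed, pairs$moving)
  names(d) <- c("fixed_x", "fixed_y", "fixed_z",
                "moving_x", "moving_y", "moving_z")
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Least-squares rigid transform from paired landmarks
#'
#' Kabsch / Umeyama solution without scaling: the rotation comes from the SVD
#' of the landmark cross-covariance with the standard reflection correction
#' (flip of the singular vector of the smallest singular value when the
#' determinant is negative). The result maps fixed points onto moving points
#' (resampling convention).
#'
#' @param pairs A [landmark_pairs()].
#' @return A [rigid_transform()].
#' @export
landmark_rigid <- function(pairs) {
  if (!inherits(pairs, "landmark_pairs")) stop("expected landmark_pairs")
  fc <- colMeans(pairs$fixed); mc <- colMeans(pairs$moving)
  A <- sweep(pairs$fixed, 2, fc)
  B <- sweep(pairs$moving, 2, mc)
  H <- crossprod(A, B)              # sum a_i b_i^T
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t <- mc - as.numeric(R %*% fc)
  rigid_transform(R, t)
}

#' Warp a volume or mask through a transform chain onto a grid
#'
#' Output voxel `x` takes the value of `moving` at `chain(x)`; this realises
#' the final "overlay the registered CECT on the CBCT" step. Use
#' `interp = "nearest"` for masks (binary output guaranteed).
#'
#' @param moving A `volume` (image or 0/1 mask).
#' @param chain A `transform_chain` (fixed -> moving) or single transform.
#' @param grid Target `grid_spec` (or `volume`).
#' @param interp `"nearest"`, `"linear"` or `"bspline3"`.
#' @param fill Out-of-extent fill value.
#' @return A `volume` on `grid`.
#' @export
warp <- function(moving, chain, grid, interp = "linear",
                 fill = min(moving$data)) {
  stopifnot_volume(moving)
  if (is_volume(grid)) grid <- grid_of(grid)
  if (!inherits(grid, "grid_spec")) stop("'grid' must be a grid_spec")
  out <- cpp_warp(moving$data, world_to_index_matrix(moving),
                  grid$shape, index_to_world_matrix(grid),
                  chain_spec(as_chain(chain)), interp_code(interp), fill)
  volume(out, grid$spacing, grid$origin, grid$direction)
}

#' Warp a binary mask (nearest neighbour, fill 0)
#' @inheritParams warp
#' @export
warp_mask <- function(moving, chain, grid) {
  warp(moving, chain, grid, interp = "nearest", fill = 0)
}

## ---- joint histogram & NMI ------------------------------------------------

#' Joint intensity histogram under a transform chain
#'
#' For each sampled fixed-grid voxel (all voxels, or a seeded uniform random
#' subset) inside `mask` whose mapped point lies inside the moving image, one
#' unit of mass is distributed over the histogram with Maes-style linear
#' partial-volume weighting (trilinear weights over the 8 surrounding moving
#' voxels). Bin edges span the min/max of contributing intensities.
#'
#' @param fixed,moving `volume`s.
#' @param chain `transform_chain` (fixed -> moving); default identity.
#' @param bins Bins per channel (>= 2).
#' @param mask Optional 0/1 `volume` on the fixed grid restricting samples.
#' @param samples Optional number of random samples (>= 1000); default all.
#' @param seed RNG seed for sampling.
#' @return An object of class `joint_histogram`: `counts` (bins x bins,
#'   fixed bins as rows), `fix_edges`, `mov_edges`, `n` contributing samples.
#' @export
joint_histogram <- function(fixed, moving, chain = transform_chain(),
                            bins = 32, mask = NULL, samples = NULL,
                            seed = 0) {
  stopifnot_volume(fixed); stopifnot_volume(moving)
  if (bins < 2) stop("bins must be >= 2")
  cand <- if (is.null(mask)) seq_along(fixed$data) else which(mask$data > 0)
  if (!is.null(samples)) {
    if (samples < 1000) stop("when sampling, use at least 1000 samples")
    if (samples < length(cand))
      cand <- with_seed(seed, sample(cand, samples))
  }
  pts <- index_to_world(fixed, linear_to_index0(cand, dim(fixed$data)))
  h <- cpp_joint_hist(fixed$data[cand], pts, chain_spec(as_chain(chain)),
                      moving$data, world_to_index_matrix(moving),
                      as.integer(bins), NULL, NULL)
  if (h$n == 0) stop("empty overlap: no sample maps inside the moving image")
  structure(list(counts = h$counts,
                 fix_edges = seq(h$fix_range[1], h$fix_range[2],
                                 length.out = bins + 1),
                 mov_edges = seq(h$mov_range[1], h$mov_range[2],
                                 length.out = bins + 1),
                 n = h$n),
            class = "joint_histogram")
}

#' @export
print.joint_histogram <- function(x, ...) {
  cat("<joint_histogram>", nrow(x$counts), "x", ncol(x$counts),
      "bins,", x$n, "samples, NMI =", signif(nmi(x), 5), "\n")
  invisible(x)
}

#' Normalized mutual information of a joint histogram
#'
#' Studholme's overlap-invariant form `(H_fixed + H_moving) / H_joint` with
#' entropies in bits from the normalised histogram (`0 log 0 = 0`). Lies in
#' `[1, 2]`: 1 under independence, 2 for identical discrete images.
#'
#' @param h A [joint_histogram()] or a non-negative counts matrix.
#' @return NMI (scalar).
#' @export
nmi <- function(h) {
  counts <- if (inherits(h, "joint_histogram")) h$counts else as.matrix(h)
  if (any(counts < 0)) stop("histogram counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) stop("empty histogram")
  p <- counts / total
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  hj <- ent(p)
  if (hj == 0) return(1)
  (ent(rowSums(p)) + ent(colSums(p))) / hj
}

## ---- configuration --------------------------------------------------------

#' Registration configuration defaults
#'
#' All the optimizer parameters the clinical description leaves open live
#' here: 64 histogram bins, a 2-level image pyramid (downsampling factors
#' 2/1) for the affine stage, a 2-level schedule for the B-spline stage
#' (control spacing 40 mm on the half-resolution image, then 20 mm at full
#' resolution), exhaustive metric sampling below `sample_cap` voxels for the
#' affine stage, capped seeded sampling for the B-spline stage, and a fixed
#' body-mask threshold so the CBCT's small field of view is not dominated by
#' background.
#'
#' @param bins Histogram bins per channel.
#' @param pyramid Downsampling factors for the affine stage, coarse to fine.
#' @param affine_maxit BFGS iteration budget per affine level.
#' @param affine_smoothing,bspline_smoothing Gaussian sigma (fixed-image
#'   voxels) applied to both images per pyramid level before metric
#'   evaluation. The affine stage uses light smoothing (its 12 parameters
#'   average noise away, and blur only biases them); the free-form stage
#'   needs heavier smoothing or it fits the CBCT noise floor.
#' @param sample_cap Use all candidate voxels when fewer than this;
#'   otherwise a seeded random subset of this size.
#' @param bspline_grid Control-point spacing (mm) per B-spline level.
#' @param bspline_pyramid Image downsampling factor per B-spline level.
#' @param bspline_samples Seeded sample size for the B-spline metric.
#' @param bspline_iterations Gradient-ascent iterations per B-spline level.
#' @param bspline_step0 Initial control-point step, mm.
#' @param regularization Bending-energy weight on control displacements.
#' @param mask_threshold Fixed-image intensity above which a voxel counts as
#'   body and may be sampled.
#' @param seed Seed for all sampling.
#' @return Named list.
#' @export
reg_config <- function(bins = 64, pyramid = c(2, 1),
                       affine_maxit = c(120, 120),
                       affine_smoothing = c(0, 0),
                       bspline_smoothing = c(1.5, 1.5),
                       sample_cap = 2e6,
                       bspline_grid = c(40, 20),
                       bspline_pyramid = c(2, 1),
                       bspline_samples = 5e4,
                       bspline_iterations = 60,
                       bspline_step0 = 2,
                       regularization = 0.001,
                       mask_threshold = -50,
                       seed = 0) {
  list(bins = bins, pyramid = pyramid, affine_maxit = affine_maxit,
       sample_cap = sample_cap, bspline_grid = bspline_grid,
       bspline_pyramid = bspline_pyramid, bspline_samples = bspline_samples,
       bspline_iterations = bspline_iterations,
       bspline_step0 = bspline_step0, regularization = regularization,
       affine_smoothing = affine_smoothing,
       bspline_smoothing = bspline_smoothing,
       mask_threshold = mask_threshold, seed = seed)
}

## run code with a temporary RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

linear_to_index0 <- function(lin, d) {
  lin0 <- lin - 1L
  cbind(lin0 %% d[1],
        (lin0 %/% d[1]) %% d[2],
        lin0 %/% (d[1] * d[2]))
}

## Gaussian smoothing (sigma in voxels) + downsampling by an integer factor.
## Smoothing is applied at every level, including factor 1: the CBCT noise
## floor otherwise dominates the fine-scale NMI landscape.
pyramid_level <- function(v, factor, sigma = factor / 2) {
  sm <- v
  if (sigma > 0) sm$data <- cpp_gauss_smooth(v$data, rep(sigma, 3))
  if (factor <= 1) return(sm)
  d <- dim(v$data)
  shape <- pmax(as.integer(ceiling(d / factor)), 2L)
  g <- grid_spec(shape, v$spacing * factor, v$origin, v$direction)
  resample_to_grid(sm, g, interp = "linear")
}

## sample candidate fixed voxels of a level: values + world points
metric_samples <- function(fixed_level, threshold, cap, seed) {
  cand <- which(fixed_level$data > threshold)
  if (length(cand) < 100) cand <- seq_along(fixed_level$data)
  if (length(cand) > cap) cand <- with_seed(seed, sample(cand, cap))
  list(values = fixed_level$data[cand],
       pts = index_to_world(fixed_level,
                            linear_to_index0(cand, dim(fixed_level$data))))
}

nmi_eval <- function(smp, chain, moving, bins, fr, mr) {
  cpp_nmi_chain(smp$values, smp$pts, chain_spec(chain), moving$data,
                world_to_index_matrix(moving), as.integer(bins), fr, mr)
}

## frozen metric ranges for a level (slightly padded)
metric_ranges <- function(smp, moving) {
  pad <- function(r) r + c(-1, 1) * 1e-6 * max(diff(r), 1)
  list(fr = pad(range(smp$values)), mr = pad(range(moving$data)))
}

## ---- affine stage ---------------------------------------------------------

par_to_affine <- function(par, center) {
  affine_transform(diag(3) + matrix(par[1:9], 3, 3), par[10:12], center)
}

#' NMI-driven affine registration
#'
#' Maximises normalized mutual information over the 12 parameters of a
#' centred affine transform by derivative-free (Nelder-Mead) ascent on a
#' coarse-to-fine image pyramid, starting from `init` (typically the
#' landmark rigid stage). The estimated affine is prepended to `init` when
#' the chain is applied, i.e. the total map is `init(affine(x))`.
#'
#' @param fixed,moving `volume`s (CBCT fixed, CECT moving).
#' @param init `transform_chain` initialisation.
#' @param config See [reg_config()].
#' @return A list of class `reg_stage`: `transform` (the
#'   [affine_transform()]), `chain` (full chain including `init`), `trace`
#'   (NMI per accepted evaluation), `nmi_initial`, `nmi_final`, `converged`.
#' @export
register_affine <- function(fixed, moving, init = transform_chain(),
                            config = reg_config()) {
  stopifnot_volume(fixed); stopifnot_volume(moving)
  init <- as_chain(init)
  center <- as.numeric(index_to_world(fixed, rbind((dim(fixed$data) - 1) / 2)))
  par <- rep(0, 12)
  trace <- numeric(0)
  nmi_init_fine <- NA_real_
  nlev <- length(config$pyramid)
  maxit <- rep(config$affine_maxit, length.out = nlev)
  smooth_sigma <- rep(config$affine_smoothing, length.out = nlev)
  for (li in seq_len(nlev)) {
    f <- config$pyramid[li]
    flev <- pyramid_level(fixed, f,
                          if (f > 1) max(f / 2, smooth_sigma[li])
                          else smooth_sigma[li])
    mlev <- pyramid_level(moving, 1, smooth_sigma[li])
    smp <- metric_samples(flev, config$mask_threshold, config$sample_cap,
                          config$seed + li)
    rng <- metric_ranges(smp, mlev)
    min_n <- 0.05 * length(smp$values)
    objective <- function(p) {
      tr <- par_to_affine(p, center)
      r <- nmi_eval(smp, transform_chain(c(list(tr), unclass(init))),
                    mlev, config$bins, rng$fr, rng$mr)
      if (!is.finite(r$nmi) || r$n < min_n) return(0)
      r$nmi
    }
    v0 <- objective(par)
    if (li == nlev) nmi_init_fine <- objective(rep(0, 12))
    pscale <- c(rep(0.02, 9), rep(2, 3))
    # quasi-Newton ascent with finite-difference gradients; the partial-volume
    # weighting makes the metric piecewise-smooth in the parameters
    opt <- tryCatch(
      stats::optim(par, objective, method = "BFGS",
                   control = list(fnscale = -1, maxit = maxit[li],
                                  parscale = pscale)),
      error = function(e) NULL)
    if (!is.null(opt) && opt$value >= v0) { par <- opt$par; v0 <- opt$value }
    trace <- c(trace, v0)
  }
  # guarantee: never worse than the initial chain on the finest level
  final <- objective_final(fixed, moving, init, par, center, config)
  converged <- TRUE
  if (final$with_affine < final$identity) {
    par <- rep(0, 12)
    converged <- FALSE
  }
  tr <- par_to_affine(par, center)
  chain <- transform_chain(c(list(tr), unclass(init)))
  structure(list(transform = tr, chain = chain, trace = trace,
                 nmi_initial = final$identity,
                 nmi_final = max(final$with_affine, final$identity),
                 converged = converged),
            class = "reg_stage")
}

objective_final <- function(fixed, moving, init, par, center, config) {
  sig <- utils::tail(rep(config$affine_smoothing,
                         length.out = length(config$pyramid)), 1)
  flev <- pyramid_level(fixed, 1, sig)
  mlev <- pyramid_level(moving, 1, sig)
  smp <- metric_samples(flev, config$mask_threshold, config$sample_cap,
                        config$seed)
  rng <- metric_ranges(smp, mlev)
  idn <- nmi_eval(smp, init, mlev, config$bins, rng$fr, rng$mr)$nmi
  tr <- par_to_affine(par, center)
  wa <- nmi_eval(smp, transform_chain(c(list(tr), unclass(init))),
                 mlev, config$bins, rng$fr, rng$mr)$nmi
  list(identity = idn, with_affine = wa)
}

#' @export
print.reg_stage <- function(x, ...) {
  cat("<reg_stage> ", class(x$transform)[1], ": NMI ",
      signif(x$nmi_initial, 5), " -> ", signif(x$nmi_final, 5),
      if (isTRUE(x$converged)) "" else " (kept initialisation)", "\n",
      sep = "")
  invisible(x)
}

## ---- B-spline stage -------------------------------------------------------

## control lattice covering the world-axis-aligned bounding box of the fixed
## image plus the cubic support margin
bspline_lattice <- function(fixed, spacing_mm) {
  d <- dim(fixed$data)
  corners <- as.matrix(expand.grid(c(0, d[1] - 1), c(0, d[2] - 1),
                                   c(0, d[3] - 1)))
  w <- index_to_world(fixed, corners)
  lo <- apply(w, 2, min); hi <- apply(w, 2, max)
  i_lo <- floor(lo / spacing_mm) - 1
  i_hi <- ceiling(hi / spacing_mm) + 2
  shape <- as.integer(i_hi - i_lo + 1)
  bspline_transform(origin = i_lo * spacing_mm, spacing = spacing_mm,
                    shape = shape)
}

## bending-energy-style penalty: mean squared second difference (mm^2) of
## the control-point displacements, with its gradient
bending_penalty <- function(coef, spacing) {
  g <- array(0, dim(coef))
  pen <- 0
  n <- 0
  for (ax in 1:3) {
    d <- dim(coef)[ax]
    if (d < 3) next
    for (comp in 1:3) {
      a <- coef[, , , comp]
      idx <- function(k) switch(ax,
        a[k, , , drop = FALSE], a[, k, , drop = FALSE], a[, , k, drop = FALSE])
      D2 <- idx(3:d) - 2 * idx(2:(d - 1)) + idx(1:(d - 2))
      pen <- pen + sum(D2^2)
      n <- n + length(D2)
      gg <- array(0, dim(a))
      add <- function(garr, k, val) {
        if (ax == 1) garr[k, , ] <- garr[k, , ] + val
        else if (ax == 2) garr[, k, ] <- garr[, k, ] + val
        else garr[, , k] <- garr[, , k] + val
        garr
      }
      s <- 2 * D2
      gg <- add(gg, 3:d, array(s, dim(D2)))
      gg <- add(gg, 2:(d - 1), -2 * array(s, dim(D2)))
      gg <- add(gg, 1:(d - 2), array(s, dim(D2)))
      g[, , , comp] <- g[, , , comp] + gg
    }
  }
  if (n == 0) return(list(value = 0, grad = g))
  list(value = pen / n, grad = g / n)
}

#' NMI-driven cubic B-spline free-form registration
#'
#' Maximises NMI over control-point displacements of a cubic B-spline
#' lattice covering the fixed-image domain, by finite-difference gradient
#' ascent with backtracking, a coarse-to-fine schedule (control spacing and
#' image resolution), and an optional bending-energy penalty. `init` must be
#' an affine-only chain (rigid and/or affine stages); the estimated
#' free-form stage is prepended to it.
#'
#' @inheritParams register_affine
#' @return A `reg_stage` list; `transform` is the [bspline_transform()].
#' @export
register_bspline <- function(fixed, moving, init = transform_chain(),
                             config = reg_config()) {
  stopifnot_volume(fixed); stopifnot_volume(moving)
  init <- as_chain(init)
  if (any(vapply(unclass(init), inherits, logical(1), "bspline_transform")))
    stop("init chain for the free-form stage must be affine-only")
  postM <- Reduce(function(M, t) {
    A <- affine_as_matrix(t)
    cbind(A[, 1:3] %*% M[, 1:3], A[, 1:3] %*% M[, 4] + A[, 4])
  }, unclass(init), init = cbind(diag(3), c(0, 0, 0)))
  nlev <- length(config$bspline_grid)
  pyr <- rep(config$bspline_pyramid, length.out = nlev)
  trace <- numeric(0)
  bt <- NULL
  nmi_initial <- NA_real_
  smooth_sigma <- rep(config$bspline_smoothing, length.out = nlev)
  for (li in seq_len(nlev)) {
    s_mm <- config$bspline_grid[li]
    flev <- pyramid_level(fixed, pyr[li], max(pyr[li] / 2, smooth_sigma[li]))
    mlev <- pyramid_level(moving, 1, smooth_sigma[li])
    if (s_mm < 2 * max(flev$spacing))
      stop("over-parameterization: control spacing ", s_mm,
           " mm is below 2 fixed voxels (", signif(2 * max(flev$spacing), 4),
           " mm)")
    new_bt <- bspline_lattice(flev, s_mm)
    if (!is.null(bt)) {
      # initialise from the previous level: displacement values at the new
      # control points (first-order coefficient transfer)
      cp <- as.matrix(expand.grid(0:(new_bt$shape[1] - 1),
                                  0:(new_bt$shape[2] - 1),
                                  0:(new_bt$shape[3] - 1)))
      xyz <- sweep(cp %*% diag(new_bt$spacing), 2, new_bt$origin, "+")
      disp <- apply_transform(bt, xyz) - xyz
      new_bt$coefficients <- array(disp, c(new_bt$shape, 3L))
    }
    bt <- new_bt
    smp <- metric_samples(flev, config$mask_threshold,
                          config$bspline_samples, config$seed + 10 + li)
    rng <- metric_ranges(smp, mlev)
    w2i <- world_to_index_matrix(mlev)
    eval_nmi <- function(coef) {
      b2 <- bt; b2$coefficients <- coef
      r <- cpp_nmi_chain(smp$values, smp$pts,
                         list(list(type = 1L, origin = b2$origin,
                                   spacing = b2$spacing, dims = b2$shape,
                                   coef = b2$coefficients),
                              list(type = 0L, M = postM)),
                         mlev$data, w2i, as.integer(config$bins),
                         rng$fr, rng$mr)
      r$nmi
    }
    coef <- bt$coefficients
    pen <- bending_penalty(coef, bt$spacing)
    cur <- eval_nmi(coef) - config$regularization * pen$value
    if (li == 1) nmi_initial <- cur + config$regularization * pen$value
    step <- config$bspline_step0
    for (it in seq_len(config$bspline_iterations)) {
      gres <- cpp_bspline_nmi_grad(smp$values, smp$pts, postM, bt$origin,
                                   bt$spacing, bt$shape, coef, mlev$data,
                                   w2i, as.integer(config$bins),
                                   rng$fr, rng$mr, 0.5)
      pen <- bending_penalty(coef, bt$spacing)
      g <- gres$grad - config$regularization * pen$grad
      gmax <- max(abs(g))
      if (gmax < 1e-12) break
      improved <- FALSE
      for (bk in 1:4) {
        cand <- coef + (step / gmax) * g
        pc <- bending_penalty(cand, bt$spacing)
        val <- eval_nmi(cand) - config$regularization * pc$value
        if (is.finite(val) && val > cur + 1e-9) {
          coef <- cand; cur <- val; improved <- TRUE
          trace <- c(trace, val)
          step <- min(step * 1.5, config$bspline_step0)
          break
        }
        step <- step / 2
      }
      if (!improved && step < 0.01) break
    }
    bt$coefficients <- coef
  }
  # guarantee on the final level samples: never worse than zero displacement
  zero <- bt; zero$coefficients[] <- 0
  n_final <- eval_final_pair(fixed, moving, bt, zero, postM, config)
  converged <- n_final$with >= n_final$without
  if (!converged) bt$coefficients[] <- 0
  chain <- transform_chain(c(list(bt), unclass(init)))
  structure(list(transform = bt, chain = chain, trace = trace,
                 nmi_initial = n_final$without,
                 nmi_final = max(n_final$with, n_final$without),
                 converged = converged),
            class = "reg_stage")
}

eval_final_pair <- function(fixed, moving, bt, zero, postM, config) {
  sig <- utils::tail(rep(config$bspline_smoothing,
                         length.out = length(config$bspline_grid)), 1)
  fixed <- pyramid_level(fixed, 1, sig)
  moving <- pyramid_level(moving, 1, sig)
  smp <- metric_samples(fixed, config$mask_threshold,
                        config$bspline_samples, config$seed)
  rng <- metric_ranges(smp, moving)
  w2i <- world_to_index_matrix(moving)
  ev <- function(b) cpp_nmi_chain(smp$values, smp$pts,
                                  list(list(type = 1L, origin = b$origin,
                                            spacing = b$spacing,
                                            dims = b$shape,
                                            coef = b$coefficients),
                                       list(type = 0L, M = postM)),
                                  moving$data, w2i,
                                  as.integer(config$bins),
                                  rng$fr, rng$mr)$nmi
  list(with = ev(bt), without = ev(zero))
}

## ---- full pipeline --------------------------------------------------------

#' Four-step CECT to CE-CBCT registration pipeline
#'
#' Runs (1) resampling of the moving CECT at CBCT resolution, (2) landmark
#' rigid initialisation, (3) NMI affine then cubic B-spline free-form
#' refinement. The returned chain maps CBCT world points to CECT world
#' points; warping the CECT (step 4) is [warp()] with this chain and the
#' CBCT grid.
#'
#' @param cbct Fixed intraprocedural CE-CBCT `volume`.
#' @param cect Moving pre-ablation CECT `volume`.
#' @param landmarks A [landmark_pairs()] (fixed = CBCT space).
#' @param config See [reg_config()].
#' @return An object of class `registration_result`: `chain`, `stages`
#'   (rigid / affine / bspline), `traces`, `nmi` per stage, `converged`
#'   flags, and the step-1 resampling grid.
#' @export
register_pipeline <- function(cbct, cect, landmarks, config = reg_config()) {
  stopifnot_volume(cbct); stopifnot_volume(cect)
  if (!inherits(landmarks, "landmark_pairs")) stop("expected landmark_pairs")
  # step 1: moving image at CBCT resolution (working overlay; the metric
  # stages sample the original CECT directly to avoid a second interpolation)
  ext <- (dim(cect$data) - 1) * cect$spacing
  shape <- pmax(as.integer(ceiling(ext / cbct$spacing)) + 1L, 2L)
  rs_grid <- grid_spec(shape, cbct$spacing, cect$origin, cect$direction)
  # step 2: landmark rigid
  rigid <- landmark_rigid(landmarks)
  # step 3a: affine
  aff <- register_affine(cbct, cect, transform_chain(list(rigid)), config)
  # step 3b: B-spline free-form
  bsp <- register_bspline(cbct, cect, aff$chain, config)
  structure(list(chain = bsp$chain,
                 stages = list(rigid = rigid, affine = aff$transform,
                               bspline = bsp$transform),
                 traces = list(affine = aff$trace, bspline = bsp$trace),
                 nmi = list(affine = c(initial = aff$nmi_initial,
                                       final = aff$nmi_final),
                            bspline = c(initial = bsp$nmi_initial,
                                        final = bsp$nmi_final)),
                 converged = c(affine = aff$converged,
                               bspline = bsp$converged),
                 resample_grid = rs_grid),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat("<registration_result> rigid + affine + B-spline chain\n")
  cat("  affine  NMI:", signif(x$nmi$affine[1], 5), "->",
      signif(x$nmi$affine[2], 5), "\n")
  cat("  bspline NMI:", signif(x$nmi$bspline[1], 5), "->",
      signif(x$nmi$bspline[2], 5), "\n")
  invisible(x)
}
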