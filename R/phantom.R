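## Synthetic paired CECT / CE-CBCT phantom -----------------------------------
##
## Stands in for patient data: a liver-like ellipsoid with a small tubular
## vessel tree (bifurcations usable as landmarks), an arterially enhancing
## tumor sphere, and a CBCT counterpart produced by a known ground-truth
## deformation (rigid + affine + smooth free-form), an added hypodense
## ablation zone, resampling to the coarser CBCT grid with a reduced field
## of view centred on the tumor, multiplicative shading and heavier noise.
## Tissue HU values are plausible arterial-phase constants; only their
## ordering (vessel > tumor > parenchyma > necrosis > background) matters to
## the algorithms.

#' Phantom configuration
#'
#' `preset = "protocol"` reproduces the clinical acquisition geometry
#' (CT 0.68 mm in-plane / 2.5 mm slices; CBCT 1.18 mm in-plane with a
#' 250 x 200 x 200 mm field of view). `preset = "bench"` keeps every tissue
#' and deformation parameter but shrinks the grids (~96^3 CT voxels) so full
#' experiments run in minutes on one core.
#'
#' @param preset `"protocol"` or `"bench"`.
#' @param ... Overrides for any returned field.
#' @return A named list of class `phantom_config`: grid spacings/FOVs (mm),
#'   liver/tumor/ablation geometry (mm), tissue HU values, per-modality
#'   noise SD (HU), CBCT shading amplitude (fractional), deformation
#'   amplitudes (`rotation_deg`, `translation_mm`, `affine_scale`,
#'   `nonrigid_amplitude` mm, `nonrigid_smoothness` mm = generating control
#'   spacing), and `seed`.
#' @export
phantom_config <- function(preset = c("protocol", "bench"), ...) {
  preset <- match.arg(preset)
  base <- list(
    ct_spacing = c(0.68, 0.68, 2.5),
    ct_fov = c(250, 200, 200),
    cbct_spacing = c(1.18, 1.18, 2.5),
    cbct_fov = c(250, 200, 200),
    liver_radii = c(95, 75, 70),
    tumor_radius = 10,
    tumor_offset = c(22, 12, 8),
    ablation_radius = 15,
    ablation_offset = c(0, 0, 0),
    vessel_radius = 3.2,
    hu = list(background = -100, parenchyma = 100, vessel = 180,
              tumor = 160, necrosis = 40),
    noise_sd_ct = 10,
    noise_sd_cbct = 25,
    shading_amplitude = 0.1,
    rotation_deg = 5,
    translation_mm = c(3, -3, 2),
    affine_scale = 1.03,
    nonrigid_amplitude = 8,
    nonrigid_smoothness = 40,
    seed = 0
  )
  if (preset == "bench") {
    base$ct_spacing <- c(1.25, 1.25, 1.4)
    base$ct_fov <- c(118, 118, 112)
    base$cbct_spacing <- c(2.1, 2.1, 2.5)
    base$cbct_fov <- c(104, 104, 96)
    base$liver_radii <- c(50, 46, 42)
    base$tumor_offset <- c(13, 7, 5)
    base$vessel_radius <- 3.2
  }
  cfg <- modifyList(base, list(...))
  if (any(unlist(cfg[c("ct_spacing", "cbct_spacing")]) <= 0))
    stop("spacings must be positive")
  if (cfg$nonrigid_smoothness < 2 * 20)
    warning("nonrigid smoothness below 2x the 20 mm recovery control ",
            "spacing; recovery may be ill-posed")
  structure(cfg, class = "phantom_config")
}

centered_grid <- function(fov, spacing) {
  shape <- pmax(as.integer(round(fov / spacing)) + 1L, 2L)
  grid_spec(shape, spacing, -(shape - 1) * spacing / 2, diag(3))
}

axis_coords <- function(g) {
  lapply(1:3, function(a) g$origin[a] + (0:(g$shape[a] - 1)) * g$spacing[a])
}

## squared-ellipsoid field on the grid: <= 1 inside
ellipsoid_field <- function(ax, center, radii) {
  A <- ((ax[[1]] - center[1]) / radii[1])^2
  B <- ((ax[[2]] - center[2]) / radii[2])^2
  C <- ((ax[[3]] - center[3]) / radii[3])^2
  outer(outer(A, B, "+"), C, "+")
}

## paint a tube (capsule) of radius r around segment p-q into mask
paint_tube <- function(mask, ax, p, q, r) {
  lo <- pmin(p, q) - r; hi <- pmax(p, q) + r
  ii <- lapply(1:3, function(a) which(ax[[a]] >= lo[a] & ax[[a]] <= hi[a]))
  if (any(lengths(ii) == 0)) return(mask)
  X <- outer(outer(ax[[1]][ii[[1]]], rep(1, length(ii[[2]]))),
             rep(1, length(ii[[3]])))
  Y <- outer(outer(rep(1, length(ii[[1]])), ax[[2]][ii[[2]]]),
             rep(1, length(ii[[3]])))
  Z <- outer(outer(rep(1, length(ii[[1]])), rep(1, length(ii[[2]]))),
             ax[[3]][ii[[3]]])
  u <- q - p; L2 <- sum(u^2)
  t <- ((X - p[1]) * u[1] + (Y - p[2]) * u[2] + (Z - p[3]) * u[3]) / L2
  t[t < 0] <- 0; t[t > 1] <- 1
  d2 <- (X - (p[1] + t * u[1]))^2 + (Y - (p[2] + t * u[2]))^2 +
        (Z - (p[3] + t * u[3]))^2
  sub <- mask[ii[[1]], ii[[2]], ii[[3]], drop = FALSE]
  sub[d2 <= r^2] <- TRUE
  mask[ii[[1]], ii[[2]], ii[[3]]] <- sub
  mask
}

## vessel tree: trunk into a main junction, three branches, sub-branches
## attached mid-branch; returns the tube mask and the bifurcation points
vessel_tree <- function(ax, center, radii, r) {
  seg <- function(p, q, rr) list(p = p, q = q, r = rr)
  rel <- function(f) center + f * radii
  J0 <- center
  B1 <- rel(c(0.55, 0.35, 0.25)); B2 <- rel(c(0.35, -0.55, 0.15))
  B3 <- rel(c(-0.30, 0.45, 0.40))
  M1 <- (J0 + B1) / 2; M2 <- (J0 + B2) / 2; M3 <- (J0 + B3) / 2
  M4 <- J0 + 0.75 * (B1 - J0); M5 <- J0 + 0.75 * (B2 - J0)
  segs <- list(
    seg(rel(c(-0.75, 0, -0.35)), J0, 1.1 * r),
    seg(J0, B1, r), seg(J0, B2, r), seg(J0, B3, r),
    seg(M1, M1 + radii * c(0.10, 0.28, -0.18), 0.7 * r),
    seg(M2, M2 + radii * c(0.18, 0.10, 0.25), 0.7 * r),
    seg(M3, M3 + radii * c(-0.18, -0.20, 0.15), 0.7 * r),
    seg(M4, M4 + radii * c(0.05, -0.22, 0.18), 0.6 * r),
    seg(M5, M5 + radii * c(-0.10, 0.15, 0.22), 0.6 * r))
  mask <- array(FALSE, lengths(ax))
  for (s in segs) mask <- paint_tube(mask, ax, s$p, s$q, s$r)
  list(mask = mask, bifurcations = rbind(J0, M1, M2, M3, M4, M5))
}

#' Generate the pre-ablation CECT phantom
#'
#' Deterministic given `cfg$seed`. Liver parenchyma ~100 HU, vessels
#' ~180 HU (arterial enhancement) with at least 3 landmarkable bifurcations,
#' a ~160 HU tumor sphere strictly inside the liver, ~-100 HU background;
#' mild partial-volume smoothing and Gaussian noise.
#'
#' @param cfg A [phantom_config()].
#' @return An object of class `liver_phantom`: `cect` (noisy volume),
#'   `cect_clean`, masks (`liver_mask`, `vessel_mask`, `tumor_mask`),
#'   `landmarks` (bifurcation points, CT world mm) and `config`.
#' @export
make_phantom <- function(cfg = phantom_config()) {
  if (!inherits(cfg, "phantom_config")) stop("expected phantom_config")
  g <- centered_grid(cfg$ct_fov, cfg$ct_spacing)
  ax <- axis_coords(g)
  liver_center <- c(0, 0, 0)
  E <- ellipsoid_field(ax, liver_center, cfg$liver_radii)
  liver <- E <= 1
  vt <- vessel_tree(ax, liver_center, cfg$liver_radii, cfg$vessel_radius)
  vessels <- vt$mask & liver
  tumor_center <- liver_center + cfg$tumor_offset
  Etum <- ellipsoid_field(ax, tumor_center, rep(cfg$tumor_radius, 3))
  tumor <- Etum <= 1
  if (any(tumor & !liver))
    stop("geometry error: tumor does not fit inside the liver")
  img <- array(cfg$hu$background, g$shape)
  img[liver] <- cfg$hu$parenchyma
  img[vessels] <- cfg$hu$vessel
  img[tumor] <- cfg$hu$tumor
  img <- cpp_gauss_smooth(img, c(0.7, 0.7, 0.7))  # partial-volume softening
  clean <- volume(img, g$spacing, g$origin, g$direction)
  noisy <- clean
  noisy$data <- noisy$data +
    with_seed(cfg$seed, array(rnorm(length(img), 0, cfg$noise_sd_ct),
                              dim(img)))
  as_mask_volume <- function(m) volume(array(as.double(m), g$shape),
                                       g$spacing, g$origin, g$direction)
  structure(list(cect = noisy, cect_clean = clean,
                 liver_mask = as_mask_volume(liver),
                 vessel_mask = as_mask_volume(vessels),
                 tumor_mask = as_mask_volume(tumor),
                 landmarks = vt$bifurcations,
                 config = cfg),
            class = "liver_phantom")
}

#' @export
print.liver_phantom <- function(x, ...) {
  cat("<liver_phantom>", paste(dim(x$cect$data), collapse = "x"),
      "CT voxels, tumor", signif(mask_volume_cm3(x$tumor_mask), 3), "cm3\n")
  invisible(x)
}

## random smooth free-form field with max displacement == amplitude (probed
## on a dense grid), lattice spacing = cfg$nonrigid_smoothness
random_ffd <- function(grid, amplitude, smoothness, seed) {
  corners <- as.matrix(expand.grid(c(0, grid$shape[1] - 1),
                                   c(0, grid$shape[2] - 1),
                                   c(0, grid$shape[3] - 1)))
  w <- index_to_world(grid, corners)
  lo <- apply(w, 2, min); hi <- apply(w, 2, max)
  i_lo <- floor(lo / smoothness) - 1
  i_hi <- ceiling(hi / smoothness) + 2
  shape <- as.integer(i_hi - i_lo + 1)
  coef <- with_seed(seed, array(runif(prod(shape) * 3, -1, 1),
                                c(shape, 3L)))
  bt <- bspline_transform(i_lo * smoothness, smoothness, shape, coef)
  if (amplitude <= 0) { bt$coefficients[] <- 0; return(bt) }
  probe <- as.matrix(expand.grid(seq(lo[1], hi[1], length.out = 24),
                                 seq(lo[2], hi[2], length.out = 24),
                                 seq(lo[3], hi[3], length.out = 24)))
  disp <- apply_transform(bt, probe) - probe
  mx <- max(sqrt(rowSums(disp^2)))
  bt$coefficients <- bt$coefficients * (amplitude / mx) * 0.999
  bt
}

rotation_about <- function(axis, deg) {
  if (deg == 0) return(diag(3))
  u <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

#' Degrade the CT phantom to its intraprocedural CE-CBCT counterpart
#'
#' Applies the ground-truth deformation (rigid + affine scaling + smooth
#' random free-form of the configured maximum amplitude), inserts a
#' hypodense ablation zone, resamples to the coarser CBCT grid with a
#' reduced field of view centred on the (deformed) tumor, and applies a
#' smooth multiplicative shading field plus heavier noise.
#'
#' @param phantom A [make_phantom()] result.
#' @param cfg Configuration; defaults to the phantom's.
#' @return A list: `cbct` (volume) and `truth` (class
#'   `phantom_ground_truth`): the exact `chain` (CBCT -> CT world),
#'   CBCT-space masks (`tumor_mask`, `liver_mask`, `ablation_mask`),
#'   `landmarks` ([landmark_pairs()], fixed = CBCT), `ablation_center`, and
#'   the config echo.
#' @export
degrade_to_cbct <- function(phantom, cfg = phantom$config) {
  if (!inherits(phantom, "liver_phantom")) stop("expected liver_phantom")
  # ground-truth chain: CBCT world -> CT world
  R <- rotation_about(c(0.3, 0.25, 0.92), cfg$rotation_deg)
  rigid <- rigid_transform(R, cfg$translation_mm)
  aff <- affine_transform(diag(3) * cfg$affine_scale, c(0, 0, 0),
                          center = c(0, 0, 0))
  cbct_grid0 <- centered_grid(cfg$cbct_fov, cfg$cbct_spacing)
  ffd <- random_ffd(cbct_grid0, cfg$nonrigid_amplitude,
                    cfg$nonrigid_smoothness, cfg$seed + 1)
  chain <- transform_chain(list(ffd, aff, rigid))
  # centre the CBCT FOV on the deformed tumor
  tumor_center_ct <- rbind(cfg$tumor_offset)
  tc_fixed <- as.numeric(invert_chain_points(chain, tumor_center_ct))
  g <- grid_spec(cbct_grid0$shape, cbct_grid0$spacing,
                 tc_fixed - (cbct_grid0$shape - 1) * cbct_grid0$spacing / 2,
                 diag(3))
  cbct <- warp(phantom$cect_clean, chain, g, interp = "linear",
               fill = cfg$hu$background)
  tumor_cbct <- warp_mask(phantom$tumor_mask, chain, g)
  liver_cbct <- warp_mask(phantom$liver_mask, chain, g)
  if (sum(tumor_cbct$data) == 0)
    stop("FOV error: deformation pushed the tumor outside the CBCT volume")
  brd <- tumor_cbct$data
  brd[2:(dim(brd)[1] - 1), 2:(dim(brd)[2] - 1), 2:(dim(brd)[3] - 1)] <- 0
  if (sum(brd) > 0)
    stop("FOV error: deformed tumor touches the CBCT field-of-view border")
  # ablation zone (CBCT space, sphere at tumor centre + offset)
  axc <- axis_coords(g)
  abl_center <- tc_fixed + cfg$ablation_offset
  abl <- ellipsoid_field(axc, abl_center, rep(cfg$ablation_radius, 3)) <= 1
  cbct$data[abl] <- cfg$hu$necrosis
  # shading: low-frequency multiplicative field
  sh_grid <- grid_spec(c(4L, 4L, 4L), (g$shape - 1) * g$spacing / 3,
                       g$origin, diag(3))
  sh_vals <- with_seed(cfg$seed + 2,
                       array(runif(64, 1 - cfg$shading_amplitude,
                                   1 + cfg$shading_amplitude), c(4, 4, 4)))
  shading <- resample_to_grid(volume(sh_vals, sh_grid$spacing, sh_grid$origin),
                              g, interp = "linear", fill = 1)
  cbct$data <- cbct$data * shading$data
  cbct$data <- cbct$data +
    with_seed(cfg$seed + 3,
              array(rnorm(prod(g$shape), 0, cfg$noise_sd_cbct), g$shape))
  # landmark pairs at vessel bifurcations
  fixed_lm <- invert_chain_points(chain, phantom$landmarks)
  resid <- apply_transform(chain, fixed_lm) - phantom$landmarks
  if (max(abs(resid)) > 1e-9)
    stop("internal error: ground-truth chain inversion did not converge")
  ablation_mask <- volume(array(as.double(abl), g$shape), g$spacing,
                          g$origin, g$direction)
  truth <- structure(list(chain = chain,
                          tumor_mask = tumor_cbct,
                          liver_mask = liver_cbct,
                          ablation_mask = ablation_mask,
                          landmarks = landmark_pairs(fixed_lm,
                                                     phantom$landmarks),
                          ablation_center = abl_center,
                          config = cfg),
                     class = "phantom_ground_truth")
  list(cbct = cbct, truth = truth)
}

#' Canonical ablation-outcome scenarios
#'
#' Emits phantom pairs for the three outcome archetypes the assessment
#' distinguishes: `complete` (ablation covers the tumor with margin),
#' `partial_25` (ablation offset tuned by bisection so ~25% of the tumor is
#' uncovered) and `missed` (disjoint ablation). Reproducible given `seed`.
#'
#' @param seed Integer seed.
#' @param preset Passed to [phantom_config()].
#' @param partial_fraction Target residual fraction of the partial scenario.
#' @return Named list of `list(phantom, cbct, truth)` per scenario.
#' @export
scenario_suite <- function(seed = 0, preset = "bench",
                           partial_fraction = 0.25) {
  base_cfg <- phantom_config(preset, seed = seed)
  ph <- make_phantom(base_cfg)
  out <- list()
  # complete: generous margin
  cfg_c <- phantom_config(preset, seed = seed,
                          ablation_radius = base_cfg$tumor_radius + 5,
                          ablation_offset = c(0, 0, 0))
  out$complete <- c(list(phantom = ph), degrade_to_cbct(ph, cfg_c))
  # partial: bisect the offset against the ground-truth digital masks
  cfg_p <- phantom_config(preset, seed = seed,
                          ablation_radius = base_cfg$tumor_radius + 2)
  pair0 <- degrade_to_cbct(ph, cfg_p)
  W <- index_to_world(pair0$truth$tumor_mask,
                      which(pair0$truth$tumor_mask$data > 0,
                            arr.ind = TRUE) - 1)
  tc <- attr_ablation_center(pair0)
  resid_frac <- function(d) {
    cen <- tc + c(d, 0, 0)
    mean(sqrt(rowSums(sweep(W, 2, cen)^2)) > cfg_p$ablation_radius)
  }
  lo <- 0; hi <- 2 * cfg_p$ablation_radius + 2 * base_cfg$tumor_radius
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (resid_frac(mid) < partial_fraction) lo <- mid else hi <- mid
  }
  cfg_p <- phantom_config(preset, seed = seed,
                          ablation_radius = base_cfg$tumor_radius + 2,
                          ablation_offset = c((lo + hi) / 2, 0, 0))
  out[[paste0("partial_", round(100 * partial_fraction))]] <-
    c(list(phantom = ph), degrade_to_cbct(ph, cfg_p))
  # missed: disjoint ablation
  cfg_m <- phantom_config(preset, seed = seed,
                          ablation_radius = base_cfg$tumor_radius,
                          ablation_offset = c(2 * base_cfg$tumor_radius + 8,
                                              0, 0))
  out$missed <- c(list(phantom = ph), degrade_to_cbct(ph, cfg_m))
  out
}

attr_ablation_center <- function(pair) {
  pair$truth$ablation_center - pair$truth$config$ablation_offset
}
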