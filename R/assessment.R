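## Quantitative ablation-outcome assessment ----------------------------------
##
## Residual tumor = warped pre-ablation tumor mask minus the ablation-zone
## mask; the minimum periablational margin (5-10 mm is the clinical adequacy
## rule) comes from Euclidean distance transforms in world mm.

round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

check_common_grid <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)) ||
      max(abs(a$spacing - b$spacing)) > 1e-9 ||
      max(abs(a$origin - b$origin)) > 1e-6 ||
      max(abs(a$direction - b$direction)) > 1e-9)
    stop("masks are not on a common grid")
}

#' Mask volume in cubic centimetres
#'
#' Foreground voxel count times the voxel volume (product of spacings),
#' converted from mm^3 to cm^3.
#'
#' @param m A 0/1 mask `volume`.
#' @return Volume in cm^3.
#' @export
mask_volume_cm3 <- function(m) {
  stopifnot_volume(m)
  sum(m$data > 0) * prod(m$spacing) / 1000
}

#' Residual-tumor assessment of an ablation
#'
#' Residual = tumor AND NOT ablation, on a common grid. The residual
#' percentage (of the initial tumor volume) is reported to 1 decimal, round
#' half away from zero. Classification: `complete` when no tumor voxel is
#' uncovered, `missed` when no tumor voxel is covered (residual 100%),
#' `partial` otherwise.
#'
#' @param tumor_warped Pre-ablation tumor mask warped onto the CBCT grid.
#' @param ablation Ablation-zone mask on the same grid.
#' @return An object of class `ablation_assessment` with fields
#'   `tumor_volume`, `ablation_volume`, `residual_volume` (cm^3),
#'   `residual_percentage`, `min_margin` (mm, negative when the tumor is not
#'   fully covered) and `classification`.
#' @export
residual_assessment <- function(tumor_warped, ablation) {
  stopifnot_volume(tumor_warped); stopifnot_volume(ablation)
  check_common_grid(tumor_warped, ablation)
  tum <- tumor_warped$data > 0
  abl <- ablation$data > 0
  if (!any(tum)) stop("empty tumor mask")
  vox_cm3 <- prod(tumor_warped$spacing) / 1000
  n_t <- sum(tum)
  n_res <- sum(tum & !abl)
  pct <- round_half_away(100 * n_res / n_t, 1)
  cls <- if (n_res == 0) "complete" else if (n_res == n_t) "missed"
         else "partial"
  margin <- if (any(abl)) min_margin(tumor_warped, ablation) else -Inf
  structure(list(tumor_volume = n_t * vox_cm3,
                 ablation_volume = sum(abl) * vox_cm3,
                 residual_volume = n_res * vox_cm3,
                 residual_percentage = pct,
                 min_margin = margin,
                 classification = cls),
            class = "ablation_assessment")
}

#' @export
print.ablation_assessment <- function(x, ...) {
  cat("<ablation_assessment>\n")
  cat(sprintf("  tumor %.2f cm3 | ablation %.2f cm3 | residual %.2f cm3 (%.1f%%)\n",
              x$tumor_volume, x$ablation_volume, x$residual_volume,
              x$residual_percentage))
  cat(sprintf("  min margin %.1f mm | classification: %s\n",
              x$min_margin, x$classification))
  invisible(x)
}

max_penetration <- function(tum, outside_abl, spacing) {
  # deepest tumor voxel outside the ablation zone: distance to nearest
  # ablation voxel, maximised over uncovered tumor voxels
  d_to_abl <- sqrt(cpp_edt_sq(!outside_abl, spacing))
  max(d_to_abl[tum & outside_abl])
}

#' Minimum periablational margin
#'
#' When the tumor is fully covered: the minimum, over tumor surface voxels
#' (foreground voxels 6-adjacent to background), of the Euclidean distance
#' (world mm, voxel centres) to the nearest voxel outside the ablation zone.
#' When it is not: minus the maximum penetration depth of tumor outside the
#' ablation zone (distance to the nearest ablation voxel).
#'
#' @param tumor_warped,ablation Non-empty masks on a common grid.
#' @return Margin in mm (negative if the tumor is not fully covered).
#' @export
min_margin <- function(tumor_warped, ablation) {
  stopifnot_volume(tumor_warped); stopifnot_volume(ablation)
  check_common_grid(tumor_warped, ablation)
  tum <- tumor_warped$data > 0
  abl <- ablation$data > 0
  if (!any(tum) || !any(abl)) stop("empty mask")
  sp <- tumor_warped$spacing
  if (any(tum & !abl)) return(-max_penetration(tum, !abl, sp))
  surf <- tum & mask_has_bg_neighbour(tum)
  if (!any(surf)) surf <- tum  # tumor fills the grid: degenerate but defined
  d_to_outside <- sqrt(cpp_edt_sq(!abl, sp))
  min(d_to_outside[surf])
}

## any of the 6 face neighbours background? (outside the array counts as
## background, so border voxels are surface)
mask_has_bg_neighbour <- function(m) {
  d <- dim(m)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  shifted <- function(o) pad[(2 + o[1]):(d[1] + 1 + o[1]),
                             (2 + o[2]):(d[2] + 1 + o[2]),
                             (2 + o[3]):(d[3] + 1 + o[3])]
  out <- array(FALSE, d)
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)))
    out <- out | !shifted(o)
  out
}

#' Retreatment decision from an assessment
#'
#' `missed`, or residual percentage at or above `threshold_pct`, calls for
#' immediate retreatment; a residual below the threshold is observed
#' (follow-up imaging); zero residual is complete. The default 20% is the
#' empirical separator between cases confirmed incomplete at 24 h and cases
#' with no residual enhancement at 24 h; 15% is an alternative supported
#' cutoff (see the vignette).
#'
#' @param a An [residual_assessment()] result.
#' @param threshold_pct Residual percentage triggering retreatment.
#' @return `"retreat"`, `"observe"` or `"complete"`.
#' @export
classify_retreatment <- function(a, threshold_pct = 20) {
  if (!inherits(a, "ablation_assessment")) stop("expected ablation_assessment")
  if (a$classification == "missed" || a$residual_percentage >= threshold_pct)
    "retreat"
  else if (a$residual_percentage > 0) "observe"
  else "complete"
}

#' Dice overlap of two masks
#' @param a,b Masks on a common grid (not both empty).
#' @return `2|a & b| / (|a| + |b|)` in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot_volume(a); stopifnot_volume(b)
  check_common_grid(a, b)
  na <- sum(a$data > 0); nb <- sum(b$data > 0)
  if (na + nb == 0) stop("Dice undefined: both masks empty")
  2 * sum(a$data > 0 & b$data > 0) / (na + nb)
}

#' Target registration error of a chain on landmark pairs
#'
#' Distance between the chain-mapped fixed points and the true moving
#' points, the quantitative surrogate for the visual position score.
#'
#' @param pairs A [landmark_pairs()].
#' @param chain A `transform_chain` (fixed -> moving).
#' @return List: `per_pair` (mm), `mean`, `max`.
#' @export
target_registration_error <- function(pairs, chain = transform_chain()) {
  if (!inherits(pairs, "landmark_pairs")) stop("expected landmark_pairs")
  mapped <- apply_transform(as_chain(chain), pairs$fixed)
  e <- sqrt(rowSums((mapped - pairs$moving)^2))
  list(per_pair = e, mean = mean(e), max = max(e))
}

#' Map a TRE (mm) to the five-point position score
#'
#' Printed scale: 1: > 7 mm, 2: 5-7 mm, 3: 3-5 mm, 4: 1-3 mm, 5: < 1 mm.
#' The interval endpoints overlap; boundary values take the better score
#' (3 mm -> 4).
#'
#' @param tre_mm Non-negative displacement in mm.
#' @return Integer score 1..5.
#' @export
tre_to_position_score <- function(tre_mm) {
  if (any(tre_mm < 0)) stop("TRE must be non-negative")
  ifelse(tre_mm <= 1, 5L,
  ifelse(tre_mm <= 3, 4L,
  ifelse(tre_mm <= 5, 3L,
  ifelse(tre_mm <= 7, 2L, 1L))))
}
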