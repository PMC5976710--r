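test_that("mask volumes convert voxel counts to cm3", {
  m <- mask_volume(array(c(rep(TRUE, 1000), rep(FALSE, 1000)), c(10, 10, 20)))
  expect_equal(mask_volume_cm3(m), 1.0)
  empty <- mask_volume(array(FALSE, c(4, 4, 4)))
  expect_equal(mask_volume_cm3(empty), 0.0)
  aniso <- volume(array(c(rep(1, 2000), rep(0, 2000)), c(20, 10, 20)),
                  spacing = c(0.5, 0.5, 2))
  expect_equal(mask_volume_cm3(aniso), 1.0)
})

test_that("residual assessment reproduces the worked clinical example", {
  # 2.1 cm3 tumor with 0.03 cm3 uncovered at 1 mm isotropic voxels
  d <- c(20, 20, 20)
  tum <- array(FALSE, d); tum[1:10, 1:15, 1:14] <- TRUE  # 2100 voxels
  abl <- tum; abl[1:10, 1, 1:3] <- FALSE                 # 30 voxels residual
  a <- residual_assessment(mask_volume(tum), mask_volume(abl))
  expect_equal(a$tumor_volume, 2.1)
  expect_equal(a$residual_volume, 0.03)
  expect_equal(a$residual_percentage, 1.4)   # 1.4286 printed to 1 decimal
  expect_equal(a$classification, "partial")
})

test_that("complete and missed ablations classify by containment", {
  E <- sphere_field(30, 14.5)
  tum <- mask_volume(E <= 8^2)
  big <- mask_volume(E <= 12^2)
  a <- residual_assessment(tum, big)
  expect_equal(a$residual_volume, 0)
  expect_equal(a$residual_percentage, 0)
  expect_equal(a$classification, "complete")
  expect_gt(a$min_margin, 0)
  far <- array(FALSE, c(30, 30, 30)); far[28:30, 28:30, 28:30] <- TRUE
  b <- residual_assessment(tum, mask_volume(far))
  expect_equal(b$residual_percentage, 100)
  expect_equal(b$classification, "missed")
  expect_lt(b$min_margin, 0)
  expect_error(residual_assessment(mask_volume(array(FALSE, c(30, 30, 30))),
                                   big), "empty tumor")
  off <- mask_volume(E <= 8^2); off$spacing <- c(2, 2, 2)
  expect_error(residual_assessment(tum, off), "common grid")
})

test_that("voxel conservation and the margin-residual equivalence hold on
           random blob pairs", {
  set.seed(17)
  for (k in 1:8) {
    A <- sphere_field(24, runif(1, 8, 14)) <= runif(1, 5, 9)^2
    B <- sphere_field(24, runif(1, 8, 14)) <= runif(1, 5, 10)^2
    if (!any(A) || !any(B)) next
    a <- residual_assessment(mask_volume(A), mask_volume(B))
    inter <- sum(A & B) / 1000
    expect_equal(a$residual_volume + inter, a$tumor_volume)
    expect_equal(a$min_margin > 0, a$residual_volume == 0)
  }
})

test_that("minimum margin matches the concentric-sphere geometry", {
  n <- 70; sp <- 0.5
  E <- sphere_field(n, (n - 1) / 2 * sp, spacing = sp)
  tum <- mask_volume(E <= 10^2, spacing = rep(sp, 3))
  abl <- mask_volume(E <= 15^2, spacing = rep(sp, 3))
  m <- min_margin(tum, abl)
  expect_lt(abs(m - 5.0), 0.5)
  same <- min_margin(tum, tum)
  expect_lte(same, sp + 1e-9)   # 0 within one voxel
  expect_gte(same, 0)
})

test_that("minimum margin matches a brute-force surface-distance oracle", {
  set.seed(19)
  n <- 20
  A <- sphere_field(n, 9, 1) <= 36
  B <- sphere_field(n, 10.2, 1) <= 64
  spc <- c(0.9, 1.1, 1.3)
  tum <- mask_volume(A, spc); abl <- mask_volume(B, spc)
  got <- min_margin(tum, abl)
  ix <- which(A, arr.ind = TRUE)
  w <- function(ind) sweep((ind - 1), 2, spc, "*")
  if (any(A & !B)) {
    # penetration: deepest uncovered tumor voxel to nearest ablation voxel
    P <- w(which(A & !B, arr.ind = TRUE)); Q <- w(which(B, arr.ind = TRUE))
    dmax <- max(apply(P, 1, function(p)
      sqrt(min(colSums((t(Q) - p)^2)))))
    expect_lt(abs(got + dmax), 1e-6)
  } else {
    surf <- A & ablafuse:::mask_has_bg_neighbour(A)
    P <- w(which(surf, arr.ind = TRUE)); Q <- w(which(!B, arr.ind = TRUE))
    dmin <- min(apply(P, 1, function(p)
      sqrt(min(colSums((t(Q) - p)^2)))))
    expect_lt(abs(got - dmin), 1e-6)
  }
})

test_that("retreatment classification follows the residual thresholds", {
  mk <- function(pct) structure(list(residual_percentage = pct,
                                     classification = if (pct == 100) "missed"
                                       else if (pct > 0) "partial"
                                       else "complete"),
                                class = "ablation_assessment")
  expect_equal(classify_retreatment(mk(28.3)), "retreat")
  expect_equal(classify_retreatment(mk(0)), "complete")
  expect_equal(classify_retreatment(mk(14.3)), "observe")
  expect_equal(classify_retreatment(mk(100)), "retreat")
  expect_equal(classify_retreatment(mk(16), threshold_pct = 15), "retreat")
  # monotone in the residual percentage
  lv <- c(complete = 0, observe = 1, retreat = 2)
  cls <- lv[sapply(c(0, 5, 15, 19.9, 20, 60, 100), function(p)
    classify_retreatment(mk(p)))]
  expect_true(all(diff(cls) >= 0))
})

test_that("Dice and TRE behave on the textbook cases", {
  E <- sphere_field(20, 9.5)
  a <- mask_volume(E <= 36)
  shell <- mask_volume(E > 36 & E <= 64)
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, shell), 0)
  empty <- mask_volume(array(FALSE, c(20, 20, 20)))
  expect_error(dice(empty, empty), "undefined")
  set.seed(23)
  P <- matrix(rnorm(12, sd = 30), 4, 3)
  th <- 0.3
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  tr <- rigid_transform(R, c(4, -2, 7))
  lp <- landmark_pairs(P, apply_transform(tr, P))
  e <- target_registration_error(lp, transform_chain(list(tr)))
  expect_lt(e$max, 1e-9)
})

test_that("the five-point position score bins TREs as printed, boundaries to
           the better score", {
  expect_equal(tre_to_position_score(0.4), 5L)
  expect_equal(tre_to_position_score(6), 2L)
  expect_equal(tre_to_position_score(7.01), 1L)
  expect_equal(tre_to_position_score(c(1, 3, 5, 7)), c(5L, 4L, 3L, 2L))
  expect_equal(tre_to_position_score(2), 4L)
  expect_error(tre_to_position_score(-1), "non-negative")
})
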