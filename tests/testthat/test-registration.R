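test_that("joint histogram concentrates on the diagonal for identical
           integer images", {
  f <- volume(array(rep(0:15, each = 500), c(20, 20, 20)))
  h <- joint_histogram(f, f, bins = 16)
  expect_equal(sum(h$counts), 8000)
  expect_equal(sum(h$counts) - sum(diag(h$counts)), 0)
  expect_equal(nmi(h), 2)
})

test_that("joint histogram equals an independently coded dense accumulation", {
  set.seed(31)
  f <- rand_volume(c(12, 12, 12), seed = 31)
  m <- rand_volume(c(12, 12, 12), spacing = c(1, 1, 1),
                   origin = c(0.3, -0.4, 0.2), seed = 32)
  ch <- transform_chain(rigid_transform(diag(3), c(0.7, -0.2, 0.5)))
  bins <- 8
  h <- joint_histogram(f, m, ch, bins = bins)
  # oracle: double loop with partial-volume weights over the 8 neighbours
  d <- dim(f$data)
  mapped <- apply_transform(ch, index_to_world(
    f, as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))))
  mi <- world_to_index(m, mapped)
  inside <- apply(mi, 1, function(x) all(x >= 0) && all(x <= 11))
  fv <- as.vector(f$data)
  tri <- function(x) {
    i0 <- pmin(pmax(floor(x), 0), 10); fr <- x - i0
    acc <- 0
    for (a in 0:1) for (b in 0:1) for (cc in 0:1)
      acc <- acc + (if (a) fr[1] else 1 - fr[1]) *
                   (if (b) fr[2] else 1 - fr[2]) *
                   (if (cc) fr[3] else 1 - fr[3]) *
                   m$data[i0[1] + a + 1, i0[2] + b + 1, i0[3] + cc + 1]
    acc
  }
  mv <- apply(mi[inside, , drop = FALSE], 1, tri)
  frange <- range(fv[inside]); mrange <- range(mv)
  bin_of <- function(v, r) pmin(pmax(floor((v - r[1]) / diff(r) * bins), 0),
                                bins - 1)
  H <- matrix(0, bins, bins)
  rows <- which(inside)
  for (q in seq_along(rows)) {
    x <- mi[rows[q], ]
    i0 <- pmin(pmax(floor(x), 0), 10); fr <- x - i0
    bf <- bin_of(fv[rows[q]], frange)
    for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
      w <- (if (a) fr[1] else 1 - fr[1]) * (if (b) fr[2] else 1 - fr[2]) *
           (if (cc) fr[3] else 1 - fr[3])
      bm <- bin_of(m$data[i0[1] + a + 1, i0[2] + b + 1, i0[3] + cc + 1],
                   mrange)
      H[bf + 1, bm + 1] <- H[bf + 1, bm + 1] + w
    }
  }
  expect_lt(max(abs(h$counts - H)), 1e-9)
  expect_equal(sum(h$counts), sum(inside))
})

test_that("NMI analytic values and invariants hold", {
  expect_equal(nmi(matrix(c(2, 0, 0, 2), 2, 2)), 2)
  expect_equal(nmi(matrix(1, 2, 2)), 1)
  # constant moving image: one occupied moving bin
  expect_equal(nmi(matrix(c(3, 5), 2, 1)), 1)
  set.seed(7)
  for (k in 1:20) {
    H <- matrix(rexp(64), 8, 8)
    expect_equal(nmi(H), nmi(t(H)))
    expect_gte(nmi(H), 1 - 1e-9)
    expect_lte(nmi(H), 2 + 1e-9)
  }
  expect_error(nmi(matrix(0, 2, 2)), "empty")
  f <- rand_volume(c(6, 6, 6))
  far <- volume(array(0, c(6, 6, 6)), origin = c(1000, 1000, 1000))
  expect_error(joint_histogram(f, far), "empty overlap")
})

test_that("warp with the identity chain reduces to resampling, keeps masks
           binary, and inverts rigid motions", {
  v <- rand_volume(c(14, 12, 10), spacing = c(1, 1.5, 2), seed = 41)
  g <- grid_spec(c(10, 10, 10), c(1.2, 1.2, 1.2), v$origin + 1)
  expect_identical(warp(v, transform_chain(), g, "linear")$data,
                   resample_to_grid(v, g, "linear")$data)
  m <- mask_volume(sphere_field(12, 5.5) <= 16)
  wm <- warp_mask(m, transform_chain(), grid_spec(c(9, 9, 9), c(1.3, 1.3, 1.3)))
  expect_true(all(wm$data %in% c(0, 1)))
  # rigid forth and back
  th <- 10 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  tr <- rigid_transform(R, c(2, -1, 1))
  inv <- rigid_transform(t(R), -as.numeric(t(R) %*% c(2, -1, 1)))
  ph <- bench_pair()$phantom
  sub <- ph$cect_clean
  w1 <- warp(sub, transform_chain(tr), grid_of(sub), "bspline3")
  w2 <- warp(w1, transform_chain(inv), grid_of(sub), "bspline3")
  core <- 15:80  # interior, away from fill regions
  err <- mean(abs(w2$data[core, core, 15:70] - sub$data[core, core, 15:70]))
  expect_lt(err, 0.02 * diff(range(sub$data)))
})

test_that("self-registration keeps the identity", {
  pair <- bench_pair()$pair
  cfg <- reg_config(seed = 1, affine_maxit = c(25, 25))
  res <- register_affine(pair$cbct, pair$cbct, transform_chain(), cfg)
  expect_lt(max(abs(res$transform$matrix - diag(3))), 1e-3)
  expect_lt(max(abs(res$transform$translation)), 0.1)
  expect_gte(res$nmi_final, res$nmi_initial)
  bsp <- register_bspline(pair$cbct, pair$cbct, transform_chain(),
                          reg_config(seed = 1, bspline_iterations = 8,
                                     bspline_samples = 2e4))
  disp <- bsp$transform$coefficients
  probe <- index_to_world(pair$cbct, as.matrix(expand.grid(
    seq(2, 48, by = 6), seq(2, 48, by = 6), seq(2, 36, by = 6))))
  moved <- apply_transform(bsp$transform, probe) - probe
  expect_lt(mean(sqrt(rowSums(moved^2))), 0.5)
  expect_gte(bsp$nmi_final, bsp$nmi_initial)
})

test_that("the B-spline stage rejects over-parameterized lattices and
           non-affine initialisations", {
  pair <- bench_pair()$pair
  expect_error(register_bspline(pair$cbct, pair$cbct, transform_chain(),
                                reg_config(bspline_grid = c(3))),
               "over-parameterization")
  bt <- bspline_transform(c(-80, -80, -80), 40, c(6, 6, 6))
  expect_error(register_bspline(pair$cbct, pair$cbct,
                                transform_chain(list(bt)), reg_config()),
               "affine-only")
})

test_that("registration stages record non-decreasing NMI and the pipeline
           improves held-out alignment monotonically from affine to B-spline", {
  bp <- bench_pair()
  ph <- bp$phantom; pair <- bp$pair
  lm3 <- clicked(pair$truth$landmarks, grid_of(pair$cbct), grid_of(ph$cect))
  cfg <- reg_config(seed = 1, affine_maxit = c(40, 40),
                    bspline_iterations = 15, bspline_samples = 2.5e4)
  res <- register_pipeline(pair$cbct, ph$cect, lm3, cfg)
  expect_gte(res$nmi$affine["final"], res$nmi$affine["initial"])
  expect_gte(res$nmi$bspline["final"], res$nmi$bspline["initial"])
  g <- grid_of(pair$cbct)
  d_aff <- dice(warp_mask(ph$tumor_mask,
                          transform_chain(list(res$stages$affine,
                                               res$stages$rigid)), g),
                pair$truth$tumor_mask)
  d_bsp <- dice(warp_mask(ph$tumor_mask, res$chain, g),
                pair$truth$tumor_mask)
  expect_gte(d_bsp, d_aff)
  held <- landmark_pairs(pair$truth$landmarks$fixed[4:6, ],
                         pair$truth$landmarks$moving[4:6, ])
  tre0 <- target_registration_error(held)$mean
  treb <- target_registration_error(held, res$chain)$mean
  expect_lt(treb, tre0)
})
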