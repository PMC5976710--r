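test_that("diffusion filter matches a dense voxel-loop oracle and its
           degenerate cases", {
  v <- rand_volume(c(8, 8, 8), seed = 1)
  v$data <- v$data * 50
  expect_identical(diffusion_filter(v, 0, 20)$data, v$data)
  flat <- volume(array(42, c(6, 6, 6)))
  expect_equal(diffusion_filter(flat, 7, 15)$data, flat$data)
  # independently coded dense update
  ref <- v$data
  g <- function(s) exp(-(s / 20)^2)
  for (it in 1:5) {
    new <- ref
    for (i in 1:8) for (j in 1:8) for (k in 1:8) {
      c0 <- ref[i, j, k]; fl <- 0
      for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                     c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
        ii <- i + o[1]; jj <- j + o[2]; kk <- k + o[3]
        if (ii >= 1 && ii <= 8 && jj >= 1 && jj <= 8 && kk >= 1 && kk <= 8) {
          df <- ref[ii, jj, kk] - c0
          fl <- fl + g(abs(df)) * df
        }
      }
      new[i, j, k] <- c0 + (1 / 6) * fl
    }
    ref <- new
  }
  expect_lt(max(abs(diffusion_filter(v, 5, 20, 1 / 6)$data - ref)), 1e-10)
  expect_error(diffusion_filter(v, 5, 20, dt = 0.3), "stability bound")
  expect_error(diffusion_filter(v, 5, kappa = -1), "kappa")
})

test_that("diffusion never increases the intensity variance", {
  v <- rand_volume(c(10, 10, 10), seed = 2)
  vs <- sapply(0:6, function(n) var(as.vector(diffusion_filter(v, n, 1)$data)))
  expect_true(all(diff(vs) <= 1e-12))
})

test_that("fast marching approximates Euclidean distance at uniform speed", {
  sp <- volume(array(1, c(41, 41, 41)))
  tt <- fast_marching(sp, rbind(c(21, 21, 21)))
  expect_identical(tt$data[21, 21, 21], 0)
  ix <- as.matrix(expand.grid(1:41, 1:41, 1:41))
  dtrue <- sqrt(rowSums((ix - 21)^2))
  sel <- dtrue > 2
  rel <- abs(as.vector(tt$data)[sel] - dtrue[sel]) / dtrue[sel]
  expect_lt(max(rel), 0.10)
})

test_that("multi-seed arrivals are the min of single-seed solutions,
           independent of seed order", {
  sp <- volume(array(1, c(25, 20, 20)), spacing = c(1, 1.5, 2))
  s1 <- c(6, 10, 10); s2 <- c(20, 8, 12)
  t1 <- fast_marching(sp, rbind(s1))
  t2 <- fast_marching(sp, rbind(s2))
  t12 <- fast_marching(sp, rbind(s1, s2))
  expect_lt(max(abs(t12$data - pmin(t1$data, t2$data))), 1e-9)
  expect_identical(t12$data, fast_marching(sp, rbind(s2, s1))$data)
  expect_error(fast_marching(sp, rbind(c(0, 1, 1))), "out of bounds")
  neg <- sp; neg$data[1] <- 0
  expect_error(fast_marching(neg, rbind(s1)), "positive")
})

test_that("geodesic active contour recovers a high-contrast sphere", {
  n <- 64
  E <- sphere_field(n, center = (n - 1) / 2)
  img <- array(0, c(n, n, n)); img[E <= 20^2] <- 100
  v <- volume(img, c(1, 1, 1))
  feat <- edge_feature(v, alpha = 5, beta = 25)
  tm <- fast_marching(feat, rbind(c(32, 32, 32)))
  init <- v; init$data <- array(as.double(tm$data <= 12), dim(img))
  seg <- geodesic_active_contour(feat, init, propagation = 1,
                                 curvature = 0.3, advection = 2,
                                 iterations = 300, dt = 0.4)
  expect_gte(dice(seg, mask_volume(E <= 20^2)), 0.95)
})

test_that("pure curvature flow shrinks a dumbbell and border inits are safe", {
  d <- c(40, 24, 24)
  axx <- 1:40; axy <- 1:24
  S1 <- outer(outer((axx - 12)^2, (axy - 12.5)^2, "+"), (axy - 12.5)^2, "+") <= 64
  S2 <- outer(outer((axx - 28)^2, (axy - 12.5)^2, "+"), (axy - 12.5)^2, "+") <= 64
  neck <- array(FALSE, d)
  for (i in 12:28) neck[i, , ] <- outer((axy - 12.5)^2, (axy - 12.5)^2, "+") <= 9
  dbm <- S1 | S2 | neck
  init <- mask_volume(dbm)
  feat <- init; feat$data[] <- 1
  out <- geodesic_active_contour(feat, init, propagation = 0, curvature = 1,
                                 advection = 0, iterations = 30, dt = 0.3)
  expect_lt(sum(out$data), sum(init$data))
  border_init <- init; border_init$data[] <- 0; border_init$data[1:4, 1:4, 1:4] <- 1
  expect_no_error(geodesic_active_contour(feat, border_init, iterations = 5))
  empty <- init; empty$data[] <- 0
  expect_error(geodesic_active_contour(feat, empty), "empty init")
})

test_that("fuzzy c-means separates well-separated groups deterministically", {
  set.seed(42)
  vals <- c(rnorm(500, 0, 1), rnorm(500, 100, 1))
  f <- fuzzy_cmeans(vals, c = 2)
  expect_lt(max(abs(f$centroids - c(0, 100))), 1.0)
  expect_lt(max(abs(rowSums(f$memberships) - 1)), 1e-6)
  expect_true(all(diff(f$centroids) > 0))
  f2 <- fuzzy_cmeans(vals, c = 2)
  expect_identical(f$centroids, f2$centroids)
  expect_error(fuzzy_cmeans(rep(5, 100), c = 2), "degenerate")
})

test_that("random walker solves the Dirichlet problem exactly on a chain and
           against a dense Laplacian oracle", {
  v <- volume(array(7, c(2, 2, 11)))
  seeds <- array(0L, c(2, 2, 11)); seeds[, , 1] <- 1L; seeds[, , 11] <- 2L
  p <- random_walker(v, seeds, beta = 0.01)
  expect_lt(max(abs(p[1, 1, , 1] - seq(1, 0, length.out = 11))), 1e-8)
  # dense oracle on a random 5^3 volume
  set.seed(5)
  v2 <- volume(array(rnorm(125, 50, 20), c(5, 5, 5)))
  seeds2 <- array(0L, c(5, 5, 5))
  seeds2[1, 1, 1] <- 1L; seeds2[5, 5, 5] <- 2L; seeds2[3, 1, 5] <- 1L
  p2 <- random_walker(v2, seeds2, beta = 0.003)
  N <- 125; W <- matrix(0, N, N)
  idx <- array(1:N, c(5, 5, 5))
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    for (o in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
      ii <- i + o[1]; jj <- j + o[2]; kk <- k + o[3]
      if (ii <= 5 && jj <= 5 && kk <= 5) {
        a <- idx[i, j, k]; b <- idx[ii, jj, kk]
        w <- exp(-0.003 * (v2$data[a] - v2$data[b])^2) + 1e-10
        W[a, b] <- w; W[b, a] <- w
      }
    }
  L <- diag(rowSums(W)) - W
  sN <- as.vector(seeds2); fr <- which(sN == 0); se <- which(sN > 0)
  M <- cbind(as.numeric(sN[se] == 1), as.numeric(sN[se] == 2))
  X <- solve(L[fr, fr], -L[fr, se] %*% M)
  P1 <- numeric(N); P1[se] <- M[, 1]; P1[fr] <- X[, 1]
  expect_lt(max(abs(as.vector(p2[, , , 1]) - P1)), 1e-8)
  # Dirichlet boundary: seeded voxels keep probability one
  expect_identical(p2[1, 1, 1, 1], 1)
  expect_identical(p2[5, 5, 5, 2], 1)
  # probabilities sum to one everywhere
  expect_lt(max(abs(apply(p2, 1:3, sum) - 1)), 1e-8)
})

test_that("random walker is equivariant under label renumbering", {
  set.seed(6)
  v <- volume(array(rnorm(216, 0, 30), c(6, 6, 6)))
  seeds <- array(0L, c(6, 6, 6))
  seeds[1, 1, 1] <- 1L; seeds[6, 6, 6] <- 2L; seeds[1, 6, 3] <- 3L
  p <- random_walker(v, seeds, beta = 0.004)
  relab <- seeds; relab[seeds == 1L] <- 7L; relab[seeds == 2L] <- 4L
  relab[seeds == 3L] <- 9L
  q <- random_walker(v, relab, beta = 0.004)
  # sorted labels: p(1,2,3) <-> q(4,7,9): 1->7 is q[,..,2], 2->4 is q[,..,1]
  expect_equal(p[, , , 1], q[, , , 2], tolerance = 1e-12)
  expect_equal(p[, , , 2], q[, , , 1], tolerance = 1e-12)
  expect_equal(p[, , , 3], q[, , , 3], tolerance = 1e-12)
  expect_error(random_walker(v, array(0L, c(6, 6, 6))), "2 distinct")
  expect_error(random_walker(v, seeds, beta = 0), "beta")
})

test_that("lesion segmentation recovers hyper- and hypodense spheres", {
  n <- 48
  E <- sphere_field(n, center = (n - 1) / 2)
  set.seed(1)
  img <- array(100, c(n, n, n)); img[E <= 10^2] <- 160
  v <- volume(img + rnorm(n^3, 0, 10), c(1, 1, 1))
  roi <- mask_volume(E <= 18^2)
  m <- segment_lesion(v, roi, "tumor")
  expect_gte(dice(m, mask_volume(E <= 10^2)), 0.90)
  expect_true(all(m$data <= roi$data))        # output within the ROI
  # hypodense ablation zone
  img2 <- array(100, c(n, n, n)); img2[E <= 12^2] <- 40
  v2 <- volume(img2 + rnorm(n^3, 0, 10), c(1, 1, 1))
  m2 <- segment_lesion(v2, mask_volume(E <= 20^2), "ablation")
  expect_gte(dice(m2, mask_volume(E <= 12^2)), 0.90)
})

test_that("noise-free two-intensity images are recovered exactly", {
  n <- 40
  E <- sphere_field(n, center = (n - 1) / 2)
  img <- array(100, c(n, n, n)); img[E <= 10^2] <- 160
  v <- volume(img, c(1, 1, 1))
  m <- segment_lesion(v, mask_volume(E <= 16^2), "tumor",
                      config = list(fcm = list(c = 2L, m = 2, tol = 1e-6)))
  expect_gte(dice(m, mask_volume(E <= 10^2)), 0.99)
  empty <- mask_volume(array(FALSE, c(n, n, n)))
  expect_error(segment_lesion(v, empty, "tumor"), "empty ROI")
})
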