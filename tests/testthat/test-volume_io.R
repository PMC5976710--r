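test_that("volume construction enforces geometry invariants", {
  expect_error(volume(matrix(0, 4, 4)), "non-3D")
  expect_error(volume(array(0, c(4, 4, 1))), "non-3D")
  expect_error(volume(array(0, c(4, 4, 4)), spacing = c(1, -1, 1)),
               "positive")
  expect_error(volume(array(0, c(4, 4, 4)), direction = matrix(1, 3, 3)),
               "orthonormal")
  v <- volume(array(0, c(4, 4, 4)), spacing = c(0.68, 0.68, 2.5),
              origin = c(-10, 5, 2))
  w <- index_to_world(v, rbind(c(1, 2, 3)))
  expect_equal(as.numeric(w), c(-10, 5, 2) + c(0.68, 0.68, 2.5) * c(1, 2, 3))
  expect_equal(world_to_index(v, w), rbind(c(1, 2, 3)))
})

test_that("NIfTI and MetaImage round-trips preserve data and geometry", {
  dirn <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3) # axis permutation
  v <- rand_volume(c(16, 16, 16), spacing = c(0.5, 1.25, 2.5),
                   origin = c(-7.5, 3.25, 12), direction = dirn, seed = 3)
  for (ext in c("nii.gz", "mha", "mhd")) {
    path <- file.path(tempdir(), paste0("rt.", ext))
    write_volume(v, path)
    r <- read_volume(path)
    expect_identical(r$data, v$data)
    expect_equal(r$spacing, v$spacing, tolerance = 1e-6)
    expect_equal(r$origin, v$origin, tolerance = 1e-5)
    expect_equal(r$direction, v$direction, tolerance = 1e-6)
  }
  # MetaImage headers carry full double precision: bit-exact geometry
  path <- file.path(tempdir(), "exact.mha")
  write_volume(v, path)
  r <- read_volume(path)
  expect_identical(r$spacing, v$spacing)
  expect_identical(r$origin, v$origin)
})

test_that("clinical CT spacing survives the NIfTI header", {
  v <- rand_volume(c(8, 8, 8), spacing = c(0.68, 0.68, 2.5), seed = 4)
  path <- file.path(tempdir(), "sp.nii.gz")
  write_volume(v, path)
  expect_equal(read_volume(path)$spacing, c(0.68, 0.68, 2.5),
               tolerance = 1e-6)
})

test_that("degenerate payloads are rejected with a format error", {
  p2d <- file.path(tempdir(), "flat.nii")
  RNifti::writeNifti(RNifti::asNifti(matrix(rnorm(64), 8, 8)), p2d)
  expect_error(read_volume(p2d), "non-3D")
  pm <- file.path(tempdir(), "flat.mha")
  writeLines(c("ObjectType = Image", "NDims = 2", "DimSize = 4 4",
               "ElementType = MET_DOUBLE", "ElementDataFile = LOCAL"), pm)
  expect_error(read_volume(pm), "non-3D")
  expect_error(read_volume(file.path(tempdir(), "nope.nii.gz")),
               "not found")
})

test_that("resampling a volume onto its own grid is the identity", {
  v <- rand_volume(c(12, 10, 9), spacing = c(1, 0.5, 2), origin = c(3, -2, 8))
  for (ip in c("nearest", "linear", "bspline3")) {
    r <- resample_to_grid(v, grid_of(v), ip)
    expect_lt(max(abs(r$data - v$data)), 1e-9)
  }
})

test_that("an integer one-voxel shift with nearest interpolation shifts and fills", {
  v <- rand_volume(c(10, 8, 8), seed = 7)
  g <- grid_spec(dim(v$data), v$spacing, v$origin + c(1, 0, 0) * v$spacing,
                 v$direction)
  r <- resample_to_grid(v, g, "nearest", fill = -77)
  expect_identical(r$data[1:9, , ], v$data[2:10, , ])
  expect_true(all(r$data[10, , ] == -77))
})

test_that("linear interpolation matches a brute-force trilinear formula", {
  v <- rand_volume(c(12, 12, 12), spacing = c(1, 0.5, 2), origin = c(-3, 4, 1),
                   seed = 11)
  tri <- function(p) {
    i <- as.numeric(world_to_index(v, rbind(p)))
    i0 <- floor(i); f <- i - i0
    acc <- 0
    for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
      w <- (if (a) f[1] else 1 - f[1]) * (if (b) f[2] else 1 - f[2]) *
           (if (cc) f[3] else 1 - f[3])
      acc <- acc + w * v$data[i0[1] + a + 1, i0[2] + b + 1, i0[3] + cc + 1]
    }
    acc
  }
  set.seed(12)
  pts <- cbind(runif(50, 0, 10), runif(50, 0, 5), runif(50, 2, 21))
  pts <- sweep(pts, 2, v$origin, "+")
  got <- ablafuse:::interp_at_world(v, pts, "linear")
  expect_lt(max(abs(got - apply(pts, 1, tri))), 1e-9)
})

test_that("linear resampling is linear in the image and respects range bounds", {
  g <- grid_spec(c(9, 9, 9), c(1.3, 1.3, 1.3), c(0.4, -0.2, 0.1))
  v1 <- rand_volume(c(12, 12, 12), seed = 21)
  v2 <- rand_volume(c(12, 12, 12), seed = 22)
  r1 <- resample_to_grid(v1, g, "linear", fill = 0)
  r2 <- resample_to_grid(v2, g, "linear", fill = 0)
  v3 <- v1; v3$data <- 2 * v1$data - 3 * v2$data
  r3 <- resample_to_grid(v3, g, "linear", fill = 0)
  expect_lt(max(abs(r3$data - (2 * r1$data - 3 * r2$data))), 1e-9)
  expect_gte(min(r1$data), min(min(v1$data), 0))
  expect_lte(max(r1$data), max(max(v1$data), 0))
})

test_that("clamp_window clips exactly and rejects ill-posed windows", {
  v <- volume(array(c(-1000, 50, 3000, rep(0, 5)), c(2, 2, 2)))
  expect_equal(clamp_window(v, -100, 300)$data[1:3], c(-100, 50, 300))
  inside <- volume(array(seq(0, 1, length.out = 8), c(2, 2, 2)))
  expect_identical(clamp_window(inside, -1, 2)$data, inside$data)
  expect_error(clamp_window(v, 0, 0), "lo < hi")
})

test_that("grid specifications serialize to JSON and back", {
  g <- grid_spec(c(5, 6, 7), c(1.18, 1.18, 2.5), c(-125, -100, -100))
  p <- file.path(tempdir(), "grid.json")
  write_grid_spec(g, p)
  r <- read_grid_spec(p)
  expect_equal(r$shape, g$shape)
  expect_equal(r$spacing, g$spacing)
  expect_equal(r$origin, g$origin)
})
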