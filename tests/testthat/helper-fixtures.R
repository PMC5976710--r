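# Shared in-code fixtures. Everything is generated; nothing binary ships.

rand_volume <- function(dims = c(16, 16, 16), spacing = c(1, 1, 1),
                        origin = c(0, 0, 0), direction = diag(3), seed = 1) {
  set.seed(seed)
  volume(array(rnorm(prod(dims)), dims), spacing, origin, direction)
}

## digital sphere mask/image helpers on an isotropic grid
sphere_field <- function(n, center, spacing = 1) {
  ax <- ((1:n) - 1) * spacing - center
  outer(outer(ax^2, ax^2, "+"), ax^2, "+")
}

mask_volume <- function(arr, spacing = c(1, 1, 1)) {
  volume(array(as.double(arr), dim(arr)), spacing)
}

## voxel-centre quantised landmark "clicks" on each scanner grid
clicked <- function(pairs, fixed_grid, moving_grid, n = 3) {
  fq <- index_to_world(fixed_grid, round(world_to_index(fixed_grid,
                                                        pairs$fixed)))
  mq <- index_to_world(moving_grid, round(world_to_index(moving_grid,
                                                         pairs$moving)))
  landmark_pairs(fq[seq_len(n), , drop = FALSE],
                 mq[seq_len(n), , drop = FALSE])
}

## one bench phantom pair, computed once per test run
bench_pair <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- make_phantom(phantom_config("bench", seed = 1))
      cache <<- list(phantom = ph, pair = degrade_to_cbct(ph))
    }
    cache
  }
})
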