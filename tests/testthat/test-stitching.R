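make_grid_fixture <- function(vol_shape = c(160, 160, 80), cols = 2,
                              rows = 2, jitter = 3, drift = "linear",
                              drift_max = 2, seed = 5, block = 16L) {
  ph <- make_phantom(vol_shape, noise_sigma = 0.01, texture = 0.35,
                     texture_sigma = 1, seed = 3)
  ts <- make_tile_stack(ph$anatomy, cols = cols, rows = rows,
                        overlap = 0.15, jitter = jitter, drift = drift,
                        drift_max = drift_max, seed = seed,
                        block_size = block)
  ts$phantom <- ph
  ts
}

test_that("edge MIPs equal brute-force strip maxima", {
  # constant tile: every MIP is that constant
  tc <- new_tile(array(2.5, c(20, 20, 10)), 1, 1, 0.15, 8L)
  mc <- extract_edge_mips(tc, 0.1, 8L)
  expect_true(all(vapply(mc$mips, function(side)
    all(vapply(side, function(m) all(m == 2.5), logical(1))),
    logical(1))))
  expect_equal(mc$n_blocks, ceiling(10 / 8))
  expect_equal(mc$strip_width, c(2, 2))  # round(0.1 * 20)
  # a single bright voxel in the left strip, block 1, appears only there
  td <- array(0, c(20, 20, 20))
  td[1, 10, 3] <- 7
  tb <- new_tile(td, 1, 1, 0.15, 8L)
  mb <- extract_edge_mips(tb, 0.1, 8L)
  expect_equal(max(mb$mips$left[[1]]), 7)
  expect_equal(max(mb$mips$left[[2]]), 0)
  expect_equal(max(mb$mips$right[[1]]), 0)
  # random tile: MIPs equal direct maxima over strip and block
  arr <- with_seed_test(3, array(stats::runif(24^3), c(24, 24, 24)))
  tr <- new_tile(arr, 1, 1, 0.15, 12L)
  mr <- extract_edge_mips(tr, 0.1, 12L)
  w <- mr$strip_width[1]
  expect_equal(mr$mips$left[[1]], apply(arr[1:w, , 1:12], 1:2, max))
  expect_equal(mr$mips$right[[2]],
               apply(arr[(24 - w + 1):24, , 13:24], 1:2, max))
  expect_equal(mr$mips$top[[1]], apply(arr[, 1:w, 1:12], 1:2, max))
  expect_error(extract_edge_mips(tr, 0.1, 0L), "block_size")
  expect_error(new_tile(arr, 1, 1, 0.7), "overlap")
})

test_that("z-column alignment recovers known shifts and flags degenerate
          input", {
  ts <- make_grid_fixture(jitter = 3, drift = "none")
  mips <- lapply(ts$grid$tiles, extract_edge_mips, edge_fraction = 0.1,
                 block_size = 16L)
  zoff <- align_z_columns(mips, search_range = 6L)
  expect_equal(unname(zoff["c2"]), ts$truth[["c2_r1"]]$dz)
  expect_equal(unname(zoff["c1"]), 0L)
  # identical columns (zero jitter): offset 0
  ts0 <- make_grid_fixture(jitter = 0, drift = "none")
  mips0 <- lapply(ts0$grid$tiles, extract_edge_mips, edge_fraction = 0.1,
                  block_size = 16L)
  expect_true(all(align_z_columns(mips0, 6L) == 0))
  # all-zero strips: degenerate-signal error
  tz <- lapply(1:2, function(c)
    new_tile(array(0, c(20, 20, 16)), c, 1, 0.15, 16L))
  names(tz) <- c("c1_r1", "c2_r1")
  mz <- lapply(tz, extract_edge_mips, edge_fraction = 0.1,
               block_size = 16L)
  expect_error(align_z_columns(mz, 4L), "degenerate")
})

test_that("x/y alignment and slice refinement recover jittered cuts within
          one voxel", {
  ts <- make_grid_fixture()
  res <- stitch_tiles(ts$grid, block_size = 16L, search_range = 6L)
  for (r in 1:2) for (c in 1:2) {
    i <- (r - 1) * 2 + c
    tr <- ts$truth[[sprintf("c%d_r%d", c, r)]]
    sl <- res$offsets$slice[[i]]
    expect_lte(max(abs(sl[, 1] - tr$dx)), 1)
    expect_lte(max(abs(sl[, 2] - tr$dy)), 1)
    expect_equal(res$offsets$dz[i], tr$dz)
  }
  # zero-jitter grid: all offsets zero
  ts0 <- make_grid_fixture(jitter = 0, drift = "none")
  res0 <- stitch_tiles(ts0$grid, block_size = 16L, search_range = 6L)
  for (i in 1:4) expect_true(all(res0$offsets$slice[[i]] == 0))
  # cycle consistency of block offsets around the 2x2 loop
  bo <- res$offsets$block
  for (b in seq_along(res$offsets$block_centers)) {
    cyc <- (bo[[2]][b, ] - bo[[1]][b, ]) + (bo[[4]][b, ] - bo[[2]][b, ]) -
      (bo[[4]][b, ] - bo[[3]][b, ]) - (bo[[3]][b, ] - bo[[1]][b, ])
    expect_lt(max(abs(cyc)), 2)
  }
})

test_that("slice-offset curve fitting reproduces exact generating curves", {
  off <- structure(list(
    block = list(cbind(c(1, 3, 5), c(2, 2, 2))),
    dz = 0, block_centers = c(8, 24, 40), block_size = 16L,
    zcount = 48L, cols = 1, rows = 1, slice = NULL, fit_residual = NULL),
    class = "tile_offsets")
  ref <- refine_slice_offsets(off, model = "linear")
  zs <- 0:47
  expect_equal(ref$slice[[1]][, 1], 1 + (zs - 8) * (2 / 16),
               tolerance = 1e-8)
  expect_equal(ref$slice[[1]][, 2], rep(2, 48), tolerance = 1e-8)
  # constant block offsets stay constant under the spline model too
  off2 <- off
  off2$block <- list(cbind(rep(4, 3), rep(-1, 3)))
  ref2 <- refine_slice_offsets(off2, model = "spline")
  expect_equal(ref2$slice[[1]][, 1], rep(4, 48), tolerance = 1e-6)
  # a sinusoidal drift sampled at many blocks is fitted within 0.5 voxel
  zc <- seq(4, 92, by = 8)
  curve <- 2 * sin(zc / 30)
  off3 <- structure(list(
    block = list(cbind(curve, 0 * curve)),
    dz = 0, block_centers = zc, block_size = 8L, zcount = 96L,
    cols = 1, rows = 1, slice = NULL, fit_residual = NULL),
    class = "tile_offsets")
  ref3 <- refine_slice_offsets(off3, model = "spline")
  truth <- 2 * sin((0:95) / 30)
  expect_lt(max(abs(ref3$slice[[1]][, 1] - truth)), 0.5)
  # single block: constant extension with a warning
  off4 <- off
  off4$block <- list(cbind(3, 1))
  off4$block_centers <- 24
  expect_warning(ref4 <- refine_slice_offsets(off4), "single block")
  expect_true(all(ref4$slice[[1]][, 1] == 3))
})

test_that("fusion reproduces sources and reads each chunk at most twice", {
  # single tile: output equals the tile
  arr <- with_seed_test(8, array(stats::runif(20^3), c(20, 20, 20)))
  t1 <- new_tile(arr, 1, 1, 0.15, 8L)
  g1 <- tile_grid(list(c1_r1 = t1), 1, 1, 0.15, block_size = 8L)
  off1 <- structure(list(block = list(matrix(0, 3, 2)), dz = 0,
                         block_centers = c(4, 12, 18), block_size = 8L,
                         zcount = 20L, cols = 1, rows = 1, slice = NULL,
                         fit_residual = NULL), class = "tile_offsets")
  f1 <- fuse(g1, off1)
  expect_equal(f1$data, arr)
  # full pipeline: two-read guarantee and single-coverage identity
  ts <- make_grid_fixture()
  res <- stitch_tiles(ts$grid, block_size = 16L, search_range = 6L)
  expect_lte(max(chunk_reads(ts$grid)), 2L)
  expect_error(fuse(ts$grid, structure(list(block = list(), dz = NULL),
                                       class = "tile_offsets")),
               "missing")
})

test_that("fusion is invariant to tile order", {
  ts <- make_grid_fixture(jitter = 1, drift = "none", seed = 2)
  res <- stitch_tiles(ts$grid, block_size = 16L, search_range = 4L)
  perm <- ts$grid
  perm$tiles <- perm$tiles[c(3, 1, 4, 2)]
  f2 <- fuse(perm, res$offsets)
  expect_equal(f2$data, res$volume$data)
})
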