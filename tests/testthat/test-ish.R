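test_that("slice preprocessing inverts and resizes with shared scaling", {
  # constant slice at the series minimum becomes constant 1 after inversion
  s0 <- matrix(0, 16, 16)
  s1 <- matrix(with_seed_test(1, stats::runif(256)), 16, 16)
  ser <- slice_series(list(s0, pmax(s1, 1e-6)), c(0, 1))
  pre <- preprocess_slices(ser, 16L)
  expect_true(all(abs(pre$slices[[1]] - 1) < 1e-12))
  # downsizing halves the resolution and doubles the pixel spacing
  big <- with_seed_test(2, slice_series(
    list(matrix(stats::runif(32^2), 32, 32),
         matrix(stats::runif(32^2), 32, 32)), c(0, 1)))
  pre2 <- preprocess_slices(big, 16L)
  expect_equal(dim(pre2$slices[[1]]), c(16L, 16L))
  expect_equal(pre2$pixel_spacing, c(2, 2))
  # inversion is an involution up to the shared rescale
  twice <- preprocess_slices(pre, 16L)
  expect_equal(1 - twice$slices[[2]], pre$slices[[2]], tolerance = 1e-12)
  expect_error(slice_series(list(), numeric(0)), "empty")
  expect_error(slice_series(list(s0, s0), c(1, 1)), "increasing")
})

test_that("spline infill reproduces stacked input when nothing is missing", {
  ph <- small_phantom(c(16, 16, 16), seed = 3)
  ser <- make_ish_series(ph$expression, step = 2, drop_fraction = 0,
                         jitter_px = 0, seed = 2)$series
  rec <- bspline_fill(ser)
  for (s in seq_along(ser$slices))
    expect_identical(rec$volume$data[, , ser$nominal_index[s]],
                     ser$slices[[s]])
  expect_true(all(rec$provenance$source == "original"))
  expect_error(bspline_fill(slice_series(list(matrix(0, 4, 4)), 0)),
               "at least 2")
})

test_that("cubic infill reproduces a linear-in-z ramp within 1 percent", {
  nz <- 20
  slices <- lapply(seq_len(nz), function(z) matrix(z / nz, 8, 8))
  present <- seq(1, nz, by = 2)
  if (!nz %in% present) present <- c(present, nz)
  ser <- slice_series(slices[present], z_positions = present,
                      nominal_index = present, n_nominal = nz)
  rec <- bspline_fill(ser, order = 3L)
  missing <- setdiff(seq_len(nz), present)
  for (mz in missing)
    expect_lt(max(abs(rec$volume$data[, , mz] - mz / nz)) / (mz / nz),
              0.01)
})

test_that("a missing slice through a Gaussian blob is filled at the
          analytic interpolant's centroid", {
  nz <- 9
  ctr <- 5
  mk <- function(z) {
    g2 <- outer((1:16 - 8)^2, (1:16 - 8)^2, "+")
    exp(-g2 / 18) * exp(-(z - ctr)^2 / 4)
  }
  present <- setdiff(1:9, 5)
  ser <- slice_series(lapply(present, mk), present, present, nz)
  rec <- bspline_fill(ser)
  filled <- rec$volume$data[, , 5]
  truth <- mk(5)
  # centroid of the filled slice within 1 pixel of the analytic one
  cx <- function(m) c(sum(row(m) * m), sum(col(m) * m)) / sum(m)
  expect_lt(max(abs(cx(filled) - cx(truth))), 1)
})

test_that("slice-wise refinement corrects in-plane jitter within a pixel", {
  ph <- small_phantom(c(24, 24, 24), seed = 5)
  ser <- make_ish_series(ph$expression, step = 2, drop_fraction = 0,
                         jitter_px = 0, seed = 3)$series
  # translate one interior slice by +4 px
  jittered <- ser
  jittered$slices[[5]] <- devatlas:::shift2d(ser$slices[[5]], 4, 0,
                                             fill = 1)
  rec <- bspline_fill(jittered)
  # reference: the clean reconstruction (mimics a well-aligned template)
  ref <- bspline_fill(ser)$volume
  refined <- slicewise_refine(rec, ref, metric = "cross_correlation")
  expect_lte(max(abs(refined$slice_shifts[5, ] - c(-4, 0))), 1)
  # refinement does not decrease adjacent-slice consistency
  adj_ncc <- function(v) {
    d <- dim(v$data)[3]
    mean(vapply(seq_len(d - 1), function(k)
      devatlas:::ncc(as.numeric(v$data[, , k]),
                     as.numeric(v$data[, , k + 1])), numeric(1)))
  }
  expect_gte(adj_ncc(refined$volume) + 1e-9, adj_ncc(rec$volume))
  # identical reference: near-zero shifts
  same <- slicewise_refine(bspline_fill(ser), ref,
                           metric = "cross_correlation")
  expect_lte(max(abs(same$slice_shifts)), 1)
})

test_that("mapping to a template lands on the template grid and recovers
          known affines", {
  ph <- small_phantom(c(24, 24, 24), seed = 6)
  ser <- make_ish_series(ph$expression, step = 2, drop_fraction = 0,
                         jitter_px = 0, seed = 4)$series
  pre <- preprocess_slices(ser, 24L)
  rec <- bspline_fill(pre)
  template <- ph$expression
  mt <- map_to_template(rec, template,
                        registration_spec(metric = "mean_squared_error"))
  expect_equal(dim(mt$mapped$data), dim(template$data))
  expect_equal(mt$mapped$spacing, template$spacing)
  expect_gt(stats::cor(as.numeric(mt$mapped$data),
                       as.numeric(template$data)), 0.95)
})

test_that("gene splitting uses only each gene's slices", {
  ph <- small_phantom(c(24, 24, 24), seed = 7)
  ser <- make_ish_series(ph$expression, step = 2, drop_fraction = 0,
                         jitter_px = 0, genes = c("A", "B"), seed = 5)$series
  pre <- preprocess_slices(ser, 24L)
  rec <- bspline_fill(pre)
  t_id <- devatlas:::identity_transform(devatlas:::vol_grid(rec$volume))
  genes <- split_genes(rec, t_id, rec$volume)
  expect_setequal(names(genes), c("A", "B"))
  provA <- attr(genes$A, "provenance")
  expect_true(all(provA$gene[provA$source == "original"] == "A"))
  # a gene with a single slice is skipped with a warning
  ser1 <- ser
  ser1$gene <- c("solo", rep("B", length(ser$slices) - 1))
  rec1 <- bspline_fill(preprocess_slices(ser1, 24L))
  expect_warning(g1 <- split_genes(rec1, t_id, rec$volume), "solo")
  expect_false("solo" %in% names(g1))
})

test_that("the full chain keeps present slices verbatim before refinement", {
  ph <- small_phantom(c(24, 24, 24), seed = 8)
  fx <- make_ish_series(ph$expression, step = 2, drop_fraction = 0.2,
                        jitter_px = 2, genes = "g", seed = 6)
  pre <- preprocess_slices(fx$series, 24L)
  rec <- bspline_fill(pre)
  for (s in seq_along(pre$slices))
    expect_identical(rec$volume$data[, , pre$nominal_index[s]],
                     pre$slices[[s]])
})
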