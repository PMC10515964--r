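test_that("count downsampling conserves totals and matches block sums", {
  ones <- image_volume(array(1, c(4, 4, 4)))
  d <- downsample_count(ones, 2)
  expect_true(all(d$data == 8))
  expect_equal(sum(d$data), 64)
  single <- image_volume(array(0, c(6, 6, 6)))
  single$data[3, 4, 5] <- 1
  ds <- downsample_count(single, 2)
  expect_equal(sum(ds$data == 1), 1)
  expect_equal(sum(ds$data), 1)
  # brute-force block-sum oracle with anisotropic factors
  b <- with_seed_test(4, array(rbinom(32^3, 1, 0.2), c(32, 32, 32)))
  v <- image_volume(b)
  r <- downsample_count(v, c(2, 2, 4))
  brute <- array(0, c(16, 16, 8))
  for (i in 1:16) for (j in 1:16) for (k in 1:8)
    brute[i, j, k] <- sum(b[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j),
                            (4 * k - 3):(4 * k)])
  expect_equal(r$data, brute)
  expect_equal(sum(r$data), sum(b))
  expect_error(downsample_count(image_volume(array(0.5, c(4, 4, 4))), 2),
               "binary")
})

test_that("regional occupancy reproduces hand-computed ratios", {
  # two regions; 12 positives in region A of 100 bins, capacity 8 per bin
  ont <- ontology(data.frame(id16 = c(1L, 2L, 3L),
                             name = c("root", "A", "B"),
                             acronym = c("rt", "A", "B"),
                             parent_id16 = c(NA, 1L, 1L)))
  lab <- array(0L, c(10, 10, 2))
  lab[, , 1] <- 2L   # region A: 100 voxels
  lab[, , 2] <- 3L   # region B: 100 voxels
  annot <- annotation_volume(image_volume(lab), ont)
  cnt <- array(0, c(10, 10, 2))
  cnt[1:3, 1:4, 1] <- 1   # 12 positive counts in A
  counts <- image_volume(cnt)
  occ <- regional_occupancy(counts, annot, voxels_per_bin = 8)
  expect_equal(occ$ratio[occ$region_id == 2], 12 / 800)
  expect_equal(occ$ratio[occ$region_id == 3], 0)
  # all-zero counts give all-zero ratios
  occ0 <- regional_occupancy(image_volume(array(0, c(10, 10, 2))), annot)
  expect_true(all(occ0$ratio == 0))
  # fully positive region at classification resolution: ratio 1
  full <- image_volume(array(8, c(10, 10, 2)))
  occf <- regional_occupancy(full, annot, voxels_per_bin = 8)
  expect_true(all(occf$ratio == 1))
})

test_that("hierarchical roll-up rows equal the sum of their children", {
  fx <- make_ontology_and_annotation(depth = 2, branching = 3,
                                     shape = c(16, 16, 16), seed = 2)
  cnt <- image_volume(array(with_seed_test(3, rpois(16^3, 1)),
                            c(16, 16, 16)))
  occ <- regional_occupancy(cnt, fx$annotation, voxels_per_bin = 1,
                            rollup = TRUE)
  ont <- fx$ontology
  for (pid in ont$table$id16[ont$table$level == 1]) {
    kids <- ont$table$id16[!is.na(ont$table$parent_id16) &
                             ont$table$parent_id16 == pid]
    kidrows <- occ[occ$region_id %in% kids, ]
    if (nrow(kidrows) == 0) next
    prow <- occ[occ$region_id == pid, ]
    expect_equal(prow$positive, sum(kidrows$positive))
    expect_equal(prow$region_voxels, sum(kidrows$region_voxels))
  }
})

test_that("occupancy is equivariant under label permutation", {
  fx <- make_ontology_and_annotation(depth = 2, branching = 2,
                                     shape = c(12, 12, 12), seed = 4)
  cnt <- image_volume(array(with_seed_test(5, rpois(12^3, 2)),
                            c(12, 12, 12)))
  occ1 <- regional_occupancy(cnt, fx$annotation, voxels_per_bin = 1)
  # permute leaf labels consistently in annotation and ontology roles
  leaves <- occ1$region_id
  perm <- with_seed_test(6, sample(leaves))
  lut <- stats::setNames(perm, leaves)
  lab2 <- fx$annotation$labels
  nz <- lab2$data != 0
  lab2$data[nz] <- lut[as.character(as.integer(lab2$data[nz]))]
  occ2 <- regional_occupancy(cnt, annotation_volume(lab2, fx$ontology),
                             voxels_per_bin = 1)
  for (i in seq_along(leaves))
    expect_equal(occ2$ratio[occ2$region_id == lut[as.character(leaves[i])]],
                 occ1$ratio[occ1$region_id == leaves[i]])
})

test_that("cell-type proportions sum to one and match per-point lookup", {
  fx <- make_ontology_and_annotation(depth = 2, branching = 3,
                                     shape = c(16, 16, 16), seed = 8)
  cells <- with_seed_test(9, data.frame(
    x_mm = runif(500, -1, 16), y_mm = runif(500, -1, 16),
    z_mm = runif(500, -1, 16),
    subclass = sample(c("sc1", "sc2", "sc3"), 500, replace = TRUE)))
  prop <- cell_type_distribution(cells, fx$annotation)
  expect_equal(unname(colSums(prop)), rep(1, ncol(prop)))
  cnt <- attr(prop, "counts")
  # brute-force per-point voxel lookup
  g <- devatlas:::vol_grid(fx$annotation$labels)
  for (i in with_seed_test(10, sample(500, 25))) {
    idx <- floor(c(cells$x_mm[i], cells$y_mm[i], cells$z_mm[i]) /
                   g$spacing - g$origin / g$spacing + 0.5)
    lab <- if (any(idx < 0) || any(idx >= g$dim)) "unassigned" else {
      l <- fx$annotation$labels$data[idx[1] + 1, idx[2] + 1, idx[3] + 1]
      if (l == 0) "unassigned" else as.character(l)
    }
    expect_gte(cnt[lab, cells$subclass[i]], 1)
  }
  # simple splits
  one <- data.frame(x_mm = 8, y_mm = 8, z_mm = 8, subclass = "s")
  p1 <- cell_type_distribution(one, fx$annotation)
  expect_equal(sum(p1), 1)
  expect_error(cell_type_distribution(one[0, ], fx$annotation), "empty")
})

test_that("a subclass split 3:1 across regions gives 0.75 / 0.25", {
  ont <- ontology(data.frame(id16 = c(1L, 2L, 3L), name = c("r", "A", "B"),
                             acronym = c("r", "A", "B"),
                             parent_id16 = c(NA, 1L, 1L)))
  lab <- array(2L, c(4, 4, 2)); lab[, , 2] <- 3L
  annot <- annotation_volume(image_volume(lab), ont)
  cells <- data.frame(x_mm = c(1, 2, 3, 1), y_mm = c(1, 1, 2, 2),
                      z_mm = c(0, 0, 0, 1), subclass = "s")
  prop <- cell_type_distribution(cells, annot)
  expect_equal(unname(prop["2", "s"]), 0.75)
  expect_equal(unname(prop["3", "s"]), 0.25)
})

test_that("MTR follows its closed form and masks nonpositive M0", {
  m0 <- image_volume(array(1, c(4, 4, 4)))
  mt <- image_volume(array(1, c(4, 4, 4)))
  expect_true(all(compute_mtr(mt, m0)$data == 0))
  mt0 <- image_volume(array(0, c(4, 4, 4)))
  expect_true(all(compute_mtr(mt0, m0)$data == 1))
  mt5 <- image_volume(array(0.5, c(4, 4, 4)))
  expect_true(all(compute_mtr(mt5, m0)$data == 0.5))
  m0bad <- image_volume(array(c(1, 0), c(4, 4, 4)))
  r <- compute_mtr(mt5, m0bad)
  expect_true(all(is.na(r$data[m0bad$data <= 0])))
  expect_error(compute_mtr(mt5, image_volume(array(1, c(5, 4, 4)))),
               "grid")
})

test_that("count warping conserves mass within tolerance", {
  ph <- small_phantom(c(24, 24, 24), seed = 3)
  b <- image_volume(array(as.numeric(ph$expression$data > 0.3), c(24, 24, 24)))
  cnt <- downsample_count(b, 2)
  g <- devatlas:::vol_grid(cnt)
  u <- devatlas:::make_smooth_field(g$dim, 1.5, seed = 5, smooth_sigma = 4)
  u <- u * 2  # mm units on the 2 mm grid
  t <- atlas_transform(diag(4), warp = u,
                       inverse_warp = devatlas:::invert_field(u, g),
                       reference = g)
  w <- warp_counts(cnt, t, reference = g)
  expect_lt(abs(sum(w$data) - sum(cnt$data)) / sum(cnt$data), 0.02)
})
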