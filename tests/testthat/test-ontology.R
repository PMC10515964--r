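mk_ont <- function() {
  ontology(data.frame(
    id16 = c(1L, 10L, 11L, 100L, 101L),
    name = c("root", "A", "B", "A1", "A2"),
    acronym = c("rt", "A", "B", "A1", "A2"),
    parent_id16 = c(NA, 1L, 1L, 10L, 10L)))
}

test_that("ontology construction assigns levels and validates the tree", {
  ont <- mk_ont()
  expect_equal(ont$table$level, c(0L, 1L, 1L, 2L, 2L))
  # orphan parent
  expect_error(ontology(data.frame(id16 = c(1, 2), name = c("r", "x"),
                                   acronym = c("r", "x"),
                                   parent_id16 = c(NA, 99))), "orphan")
  # self-parent cycle
  expect_error(ontology(data.frame(id16 = c(1, 2), name = c("r", "x"),
                                   acronym = c("r", "x"),
                                   parent_id16 = c(NA, 2))), "cycle")
  # duplicate ids
  expect_error(ontology(data.frame(id16 = c(1, 1), name = c("r", "x"),
                                   acronym = c("r", "x"),
                                   parent_id16 = c(NA, 1))), "duplicate")
  # two-node mutual cycle
  expect_error(ontology(data.frame(id16 = c(1, 2, 3), name = c("r", "x", "y"),
                                   acronym = c("r", "x", "y"),
                                   parent_id16 = c(NA, 3, 2))), "cycle")
})

test_that("ontology CSV round trip", {
  ont <- mk_ont()
  path <- file.path(tmp_dir(), "ont.csv")
  utils::write.csv(ont$table, path, row.names = FALSE, na = "")
  ont2 <- load_ontology(path)
  expect_equal(ont2$table$id16, ont$table$id16)
  expect_equal(ont2$table$level, ont$table$level)
})

test_that("id remapping matches the digit-slicing rule", {
  expect_identical(remap_id32_to_16(15565), 15565L)   # in range: identity
  expect_identical(as.integer(remap_id32_to_16(126651558)), 21558L)
  # string-slicing oracle over random out-of-range ids
  ids <- with_seed_test(11, sample(65536:2147000000, 1e4))
  got <- suppressWarnings(vapply(ids, function(i)
    as.integer(remap_id32_to_16(i)), integer(1)))
  oracle <- as.integer(paste0("2", substr(sprintf("%010d", ids), 7, 10)))
  expect_identical(got, oracle)
  expect_true(all(got >= 20000 & got <= 29999))
  # identity below 65536
  small <- with_seed_test(12, sample(0:65535, 1e3))
  expect_identical(as.integer(remap_id32_to_16(small)), small)
})

test_that("remap collisions raise instead of renumbering", {
  expect_error(remap_id32_to_16(c(70001, 12370001)), "collision")
  expect_error(remap_id32_to_16(-1), "negative")
  # an in-range id colliding with a remapped one also raises
  expect_error(remap_id32_to_16(c(20001, 70001)), "collision")
})

test_that("annotation validation reports exactly the seeded violations", {
  fx <- make_ontology_and_annotation(depth = 2, branching = 3,
                                     shape = c(20, 20, 20), seed = 3)
  rep0 <- validate_annotation(fx$annotation, fx$mask)
  expect_true(rep0$pass)
  fx3 <- make_ontology_and_annotation(depth = 2, branching = 3,
                                      shape = c(20, 20, 20), seed = 3,
                                      corrupt = 3)
  rep3 <- validate_annotation(fx3$annotation, fx3$mask)
  expect_false(rep3$pass)
  expect_length(rep3$unlabeled_in_mask, 3)
  # unknown label finding
  bad <- fx$annotation$labels
  inmask <- which(fx$mask$data > 0)[1]
  bad$data[inmask] <- 9999
  rep_u <- validate_annotation(bad, fx$mask, fx$ontology)
  expect_true(9999 %in% rep_u$unknown_labels)
  # label outside the mask
  outv <- which(fx$mask$data == 0)[1]
  bad2 <- fx$annotation$labels
  bad2$data[outv] <- fx$ontology$table$id16[2]
  rep_o <- validate_annotation(bad2, fx$mask, fx$ontology)
  expect_length(rep_o$labeled_outside_mask, 1)
})

test_that("level aggregation conserves voxel counts and matches the
          per-voxel ancestor oracle", {
  fx <- make_ontology_and_annotation(depth = 3, branching = 2,
                                     shape = c(16, 16, 16), seed = 5)
  ont <- fx$ontology
  lab <- as.integer(fx$annotation$labels$data)
  for (lev in 0:2) {
    agg <- aggregate_to_level(fx$annotation, lev)
    expect_equal(sum(agg$labels$data != 0), sum(lab != 0))
    # brute-force per-voxel ancestor walk
    oracle <- vapply(lab, function(id) {
      if (id == 0L) return(0L)
      cur <- id
      while (ont$level[as.character(cur)] > lev)
        cur <- ont$parent[as.character(cur)]
      as.integer(cur)
    }, integer(1))
    expect_identical(as.integer(agg$labels$data), oracle)
  }
  # aggregating to a label's own level leaves it unchanged
  own <- aggregate_to_level(fx$annotation, max(ont$table$level))
  expect_identical(own$labels$data, fx$annotation$labels$data)
})

test_that("crosstab marginals equal region volumes exactly", {
  fx <- make_ontology_and_annotation(depth = 2, branching = 3,
                                     shape = c(16, 16, 16), seed = 7)
  a <- fx$annotation
  # identical annotations give a diagonal table
  tab <- crosstab_labels(a, a)
  expect_true(all(tab[upper.tri(tab)] == 0) && all(tab[lower.tri(tab)] == 0))
  # random relabeling of B: marginals must equal region volumes
  b_lab <- a$labels
  ids <- unique(as.integer(b_lab$data))
  lut <- stats::setNames(with_seed_test(8, sample(ids)), ids)
  b_lab$data[] <- lut[as.character(as.integer(b_lab$data))]
  tabs <- crosstab_labels(a$labels, b_lab)
  va <- table(as.integer(a$labels$data))
  vb <- table(as.integer(b_lab$data))
  expect_equal(rowSums(tabs)[names(va)], c(va)[names(va)],
               ignore_attr = TRUE)
  expect_equal(colSums(tabs)[names(vb)], c(vb)[names(vb)],
               ignore_attr = TRUE)
  # brute-force per-voxel tally oracle
  long <- crosstab_labels(a$labels, b_lab, as_long = TRUE)
  pick <- long[with_seed_test(9, sample(nrow(long), 5)), ]
  for (r in seq_len(nrow(pick)))
    expect_equal(pick$voxels[r],
                 sum(a$labels$data == as.integer(pick$label_a[r]) &
                       b_lab$data == as.integer(pick$label_b[r])))
})

test_that("new-structure id allocation stays inside 18000-19999", {
  ont <- mk_ont()
  ids <- allocate_new_ids(ont, 5)
  expect_true(all(ids >= 18000 & ids <= 19999))
  expect_error(allocate_new_ids(ont, 3000), "exhausted")
})
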