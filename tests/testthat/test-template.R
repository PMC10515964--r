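test_that("midsagittal reflection is an exact involution", {
  v <- rand_volume(c(10, 8, 6), seed = 2)
  r <- reflect_midsagittal(v)
  expect_identical(reflect_midsagittal(r)$data, v$data)
  # marked voxel at 0-based x index 2 of 10 moves to x index 7
  m <- image_volume(array(0, c(10, 8, 6)))
  m$data[3, 4, 5] <- 1
  rm_ <- reflect_midsagittal(m)
  expect_equal(rm_$data[8, 4, 5], 1)
  expect_equal(sum(rm_$data), 1)
  sym <- make_phantom(c(16, 16, 16), noise_sigma = 0, seed = 1)
  expect_equal(reflect_midsagittal(sym$anatomy)$data, sym$anatomy$data)
  bad <- v
  bad$orientation <- "SAR"
  expect_error(reflect_midsagittal(bad), "left-right")
})

test_that("symmetrization doubles the cohort with consistent flags", {
  ph <- small_phantom(c(12, 12, 12))
  recs <- lapply(1:6, function(i)
    subject_record(paste0("s", i), ph$anatomy,
                   list(t2w = ph$mask)))
  ch <- symmetrize_cohort(cohort(recs))
  expect_length(ch$records, 12)
  refl <- vapply(ch$records, `[[`, logical(1), "reflected")
  expect_equal(sum(refl), 6)
  # sibling contrasts reflected consistently with the primary
  r7 <- ch$records[[7]]
  expect_equal(r7$primary$data, reflect_midsagittal(ph$anatomy)$data)
  expect_equal(r7$contrasts$t2w$data, reflect_midsagittal(ph$mask)$data)
  expect_length(symmetrize_cohort(cohort())$records, 0)
})

test_that("a cohort of identical images returns that image with identity
          transforms", {
  ph <- small_phantom(c(16, 16, 16), seed = 5)
  ch <- cohort(lapply(1:3, function(i)
    subject_record(paste0("i", i), ph$anatomy)))
  res <- build_template(ch, registration_spec(mode = "nonlinear"),
                        n_iter = 2)
  expect_lt(max(abs(res$template$data - ph$anatomy$data)), 1e-6)
  g <- res$grid
  expect_lt(max_disp_vox(res$transforms[[1]], g), 0.1)
  expect_equal(nrow(res$convergence) >= 1, TRUE)
})

test_that("a +d/-d shifted pair centers the template on the unshifted
          phantom", {
  ph <- make_phantom(c(24, 24, 24), noise_sigma = 0.005, seed = 4)
  g <- devatlas:::vol_grid(ph$anatomy)
  mk <- function(d) apply_transform(ph$anatomy,
                                    devatlas:::translation_transform(d),
                                    reference = g)
  ch <- cohort(list(subject_record("a", mk(c(2, 0, 0))),
                    subject_record("b", mk(c(-2, 0, 0)))))
  res <- build_template(ch, registration_spec(mode = "nonlinear"),
                        n_iter = 3)
  sh <- cross_correlate_shift(ph$anatomy$data, res$template$data)
  expect_lt(max(abs(sh)), 1)
})

test_that("symmetrized cohorts give mirror-symmetric templates with a
          centered mean field", {
  ph <- make_phantom(c(24, 24, 24), noise_sigma = 0.01, seed = 4)
  mc <- make_cohort(ph, n = 3, deform_magnitude = 2, seed = 11)
  ch <- symmetrize_cohort(mc$cohort)
  res <- build_template(ch, registration_spec(mode = "nonlinear"),
                        n_iter = 2)
  expect_lt(mirror_asymmetry(res$template), 0.01)
  g <- res$grid
  fields <- lapply(res$transforms,
                   function(t) devatlas:::total_displacement_on(t, g))
  mf <- Reduce(`+`, fields) / length(fields)
  expect_lt(max(sqrt(apply(mf^2, 1:3, sum))), 0.5)
  # determinism: an identical build gives a bit-identical convergence record
  res2 <- build_template(ch, registration_spec(mode = "nonlinear"),
                         n_iter = 2)
  expect_identical(res$convergence, res2$convergence)
})

test_that("contrast propagation reuses transforms and stays linear", {
  ph <- small_phantom(c(16, 16, 16), seed = 6)
  mc <- make_cohort(ph, n = 3, deform_magnitude = 1.5, seed = 3,
                    contrasts = list(same = identity,
                                     twice = function(x) 2 * x))
  res <- build_template(mc$cohort, registration_spec(mode = "nonlinear"),
                        n_iter = 2)
  res <- propagate_contrasts(res, mc$cohort)
  expect_equal(res$contrast_templates$same$data, res$template$data,
               tolerance = 1e-12)
  expect_equal(res$contrast_templates$twice$data, 2 * res$template$data,
               tolerance = 1e-12)
  expect_equal(unname(res$contrast_counts), c(3L, 3L))
})

test_that("missing contrasts follow the configured policy", {
  ph <- small_phantom(c(12, 12, 12), seed = 7)
  g <- devatlas:::vol_grid(ph$anatomy)
  recs <- lapply(1:4, function(i) {
    contrasts <- if (i <= 3) list(fa = image_volume(ph$anatomy$data * i,
                                                    g$spacing)) else list()
    subject_record(paste0("s", i), ph$anatomy, contrasts)
  })
  ch <- cohort(recs)
  res <- build_template(ch, registration_spec(mode = "nonlinear"),
                        n_iter = 1)
  res_skip <- propagate_contrasts(res, ch, missing_policy = "skip")
  expect_equal(unname(res_skip$contrast_counts["fa"]), 3L)
  # identical-image cohort: transforms are identity, so the average is the
  # hand-computed mean of the three present contrasts
  expect_equal(res_skip$contrast_templates$fa$data,
               ph$anatomy$data * mean(1:3), tolerance = 1e-6)
  expect_error(propagate_contrasts(res, ch, missing_policy = "error"),
               "missing")
})

test_that("staged multiresolution building refines coarse templates", {
  ph <- small_phantom(c(24, 24, 24), seed = 8)
  mc <- make_cohort(ph, n = 2, deform_magnitude = 1.5, seed = 5)
  expect_error(staged_multires_build(mc$cohort, c(1, 2)), "decrease")
  # identical-image cohort: staged build returns the image at fine spacing
  chi <- cohort(lapply(1:2, function(i)
    subject_record(paste0("i", i), ph$anatomy)))
  res <- staged_multires_build(chi, c(2, 1),
                               registration_spec(mode = "nonlinear"),
                               n_iter = 1)
  expect_equal(dim(res$template$data), dim(ph$anatomy$data))
  expect_gt(stats::cor(as.numeric(res$template$data),
                       as.numeric(ph$anatomy$data)), 0.999)
  expect_length(res$stages, 2)
  # one-stage call at native spacing equals build_template
  r1 <- staged_multires_build(mc$cohort, 1,
                              registration_spec(mode = "nonlinear"),
                              n_iter = 1)
  r2 <- build_template(mc$cohort, registration_spec(mode = "nonlinear"),
                       n_iter = 1)
  expect_equal(r1$template$data, r2$template$data, tolerance = 1e-10)
})
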