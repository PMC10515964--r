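test_that("modified masks subtract regions with exact voxel accounting", {
  shape <- c(20, 20, 20)
  idx <- arrayInd(seq_len(prod(shape)), shape) - 1L
  ell <- image_volume(array(as.numeric(
    rowSums(sweep(idx, 2, (shape - 1) / 2)^2 / (8^2)) <= 1), shape))
  # no regions: output equals the brain mask
  mm0 <- build_modified_mask(ell, list())
  expect_equal(mm0$mask$data, ell$data)
  # two disjoint cubes: count identity
  c1 <- image_volume(array(0, shape)); c1$data[8:10, 8:10, 8:10] <- 1
  c2 <- image_volume(array(0, shape)); c2$data[12:13, 8:9, 10:11] <- 1
  mm <- build_modified_mask(ell, list(c1, c2))
  expect_equal(sum(mm$mask$data), sum(ell$data) - 27 - 8)
  expect_equal(mm$region_voxels, c(27L, 8L))
  # region equal to the brain mask empties it, with a warning
  expect_warning(mme <- build_modified_mask(ell, list(ell)), "empty")
  expect_equal(sum(mme$mask$data), 0)
  # region poking outside the brain is clipped with a warning
  pok <- image_volume(array(0, shape)); pok$data[1:3, 1:3, 1:3] <- 1
  expect_warning(build_modified_mask(ell, list(pok)), "clipped")
})

test_that("mask-assisted registration corrects an internally displaced
          structure at least twice as well as image-only", {
  fx <- make_multimodal_pair()
  g <- devatlas:::vol_grid(fx$fixed)
  t_img <- initial_multimodal_register(fx$fixed, fx$moving)
  e_img <- sqrt(sum((centroid_of(apply_transform(fx$moving_structure,
                                                 t_img, reference = g)) -
                       centroid_of(fx$fixed_structure))^2))
  t_mask <- landmark_assisted_register(fx$fixed, fx$moving, fx$fixed_mask,
                                       fx$moving_mask)
  e_mask <- sqrt(sum((centroid_of(apply_transform(fx$moving_structure,
                                                  t_mask, reference = g)) -
                        centroid_of(fx$fixed_structure))^2))
  expect_gte(e_img / e_mask, 2)
  d_img <- dice_overlap(fx$fixed_brain,
                        apply_transform(fx$moving_brain, t_img,
                                        reference = g,
                                        interpolation = "nearest"))
  d_mask <- dice_overlap(fx$fixed_brain,
                         apply_transform(fx$moving_brain, t_mask,
                                         reference = g,
                                         interpolation = "nearest"))
  expect_gte(d_mask, d_img)
})

test_that("equal channel weighting is order invariant", {
  fx <- make_multimodal_pair(shape = c(32, 32, 32),
                             displacement = c(4, 0, 0), seed = 9)
  spec <- registration_spec(mode = "nonlinear",
                            channel_weights = c(0.5, 0.5))
  fm <- devatlas:::mask_distance(fx$fixed_mask$mask, 2)
  mm <- devatlas:::mask_distance(fx$moving_mask$mask, 2)
  t_ab <- register(list(fx$fixed, fm), list(fx$moving, mm), spec)
  t_ba <- register(list(fm, fx$fixed), list(mm, fx$moving), spec)
  diff <- sqrt(apply((t_ab$warp - t_ba$warp)^2, 1:3, sum))
  expect_lt(mean(diff), 0.1)
})

test_that("identical inputs give identity multimodal registration and
          disjoint fields of view error", {
  ph <- small_phantom(c(20, 20, 20), seed = 3)
  t <- initial_multimodal_register(ph$anatomy, ph$anatomy)
  g <- devatlas:::vol_grid(ph$anatomy)
  expect_lt(max_disp_vox(t, g), 0.5)
  far <- ph$anatomy
  far$origin <- c(1000, 1000, 1000)
  expect_error(initial_multimodal_register(ph$anatomy, far), "overlap")
  expect_error(landmark_assisted_register(
    ph$anatomy, ph$anatomy,
    image_volume(array(0, c(20, 20, 20))),
    image_volume(array(0, c(20, 20, 20)))), "empty mask")
})

test_that("warp resampling applies once to many payloads, preserving
          labels and statelessness", {
  ph <- small_phantom(c(20, 20, 20), seed = 5)
  g <- devatlas:::vol_grid(ph$anatomy)
  u <- devatlas:::make_smooth_field(g$dim, 2, seed = 4)
  t <- atlas_transform(diag(4), warp = u,
                       inverse_warp = devatlas:::invert_field(u, g),
                       reference = g)
  lab <- image_volume(array(with_seed_test(3, sample(c(0L, 5L, 9L),
                                                     prod(g$dim),
                                                     replace = TRUE)),
                            g$dim))
  outs <- resample_and_apply(t, 2, list(ph$anatomy, lab),
                             interpolation = c("linear", "nearest"))
  expect_equal(outs[[1]]$spacing, c(2, 2, 2))
  expect_true(all(unique(as.integer(outs[[2]]$data)) %in%
                    unique(as.integer(lab$data))))
  # identical results when called payload by payload
  o1 <- resample_and_apply(t, 2, list(ph$anatomy), "linear")
  expect_equal(o1[[1]]$data, outs[[1]]$data)
})

test_that("annotation backprojection is exact for identity and whole-voxel
          translations and >= 95% for smooth warps", {
  fx <- make_ontology_and_annotation(depth = 1, branching = 4,
                                     shape = c(24, 24, 24), seed = 6)
  lab <- fx$annotation$labels
  g <- devatlas:::vol_grid(lab)
  idt <- devatlas:::identity_transform(g)
  expect_equal(backproject_annotations(lab, idt, reference = g)$data,
               lab$data)
  tr <- devatlas:::translation_transform(c(2, 0, 0))
  tr$reference <- g
  back <- backproject_annotations(lab, tr, reference = g)
  expect_equal(back$data[3:24, , ], lab$data[1:22, , ])
  # smooth warp round trip: A -> B -> A label agreement on the brain
  u <- devatlas:::make_smooth_field(g$dim, 1.5, seed = 9, smooth_sigma = 10)
  t <- atlas_transform(diag(4), warp = u,
                       inverse_warp = devatlas:::invert_field(u, g),
                       reference = g)
  fwd <- apply_transform(lab, t, reference = g, interpolation = "nearest")
  back2 <- backproject_annotations(fwd, t, reference = g)
  m <- fx$mask$data > 0
  expect_gte(mean(back2$data[m] == lab$data[m]), 0.95)
  no_inv <- atlas_transform(diag(4), warp = u, reference = g)
  no_inv$inverse_warp <- NULL
  expect_error(backproject_annotations(lab, no_inv, reference = g),
               "inverse")
})

test_that("stereotaxic frames are rigid and recover known geometry", {
  ph <- small_phantom(c(20, 20, 20), seed = 2)
  # already aligned: bregma at origin, lambda caudal along -y
  fr0 <- to_stereotaxic(ph$anatomy, c(0, 0, 0), c(0, -4, 0))
  expect_lt(max(abs(fr0$transform$affine - diag(4))), 1e-10)
  expect_lt(fr0$rotation_deg, 1e-6)
  # 30 degree rotation in the sagittal (y-z) plane
  th <- 30 * pi / 180
  lam <- c(0, -4 * cos(th), -4 * sin(th))
  fr <- to_stereotaxic(ph$anatomy, c(1, 2, 3), c(1, 2, 3) + lam)
  expect_equal(fr$rotation_deg, 30, tolerance = 0.1)
  R <- fr$transform$affine[1:3, 1:3]
  expect_equal(det(R), 1, tolerance = 1e-10)
  expect_equal(t(R) %*% R, diag(3), tolerance = 1e-10)
  # bregma maps to the origin of the frame
  expect_equal(as.numeric(devatlas:::map_points(fr$transform,
                                                matrix(0, 1, 3))),
               c(1, 2, 3))
  # bregma-lambda distance is preserved (isometry)
  p <- devatlas:::map_points(fr$transform, rbind(c(0, 0, 0), c(0, -4, 0)))
  expect_equal(sqrt(sum((p[1, ] - p[2, ])^2)), 4, tolerance = 1e-10)
  expect_error(to_stereotaxic(ph$anatomy, c(1, 1, 1), c(1, 1, 1)),
               "coincide")
})
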