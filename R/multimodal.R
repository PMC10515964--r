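#' Initial multimodal registration
#'
#' Convenience front end for aligning a template of one modality to a
#' template of another (e.g. light-sheet autofluorescence to MRI): mutual
#' information metric, linear then nonlinear.
#'
#' @param fixed,moving [image_volume]s.
#' @param spec optional [registration_spec()] override; its metric/mode
#'   are forced to mutual information / linear-then-nonlinear.
#' @return an [atlas_transform].
#' @export
initial_multimodal_register <- function(fixed, moving, spec = NULL) {
  if (is.null(spec)) spec <- registration_spec()
  spec$metric <- "mutual_information"
  spec$mode <- "linear_then_nonlinear"
  if (!overlap_plausible(fixed, moving))
    stop("initial_multimodal_register: fields of view do not overlap",
         call. = FALSE)
  register(fixed, moving, spec)
}

overlap_plausible <- function(a, b) {
  ga <- vol_grid(a); gb <- vol_grid(b)
  lo <- pmax(ga$origin, gb$origin)
  hi <- pmin(ga$origin + grid_extent(ga), gb$origin + grid_extent(gb))
  all(hi > lo)
}

#' Modified brain mask for landmark-assisted registration
#'
#' Subtracts segmented misaligned-region masks from a whole-brain mask,
#' carving identifiable boundaries around regions that an intensity-only
#' registration left misaligned. Regions extending outside the brain mask
#' are clipped with a warning.
#'
#' @param brain_mask binary [image_volume].
#' @param misaligned_regions list of binary [image_volume]s on the same
#'   grid.
#' @return a `modified_mask`: `mask` (binary [image_volume]), `regions`
#'   (the clipped inputs) and per-region voxel counts.
#' @export
build_modified_mask <- function(brain_mask, misaligned_regions = list()) {
  stopifnot(is_image_volume(brain_mask))
  bm <- brain_mask$data > 0
  clipped <- list()
  counts <- integer(0)
  acc <- array(FALSE, dim(bm))
  for (i in seq_along(misaligned_regions)) {
    r <- misaligned_regions[[i]]
    if (!same_grid(r, brain_mask))
      stop("build_modified_mask: region ", i, " on a different grid",
           call. = FALSE)
    rm_ <- r$data > 0
    if (any(rm_ & !bm)) {
      warning("build_modified_mask: region ", i,
              " extends outside the brain mask; clipped", call. = FALSE)
      rm_ <- rm_ & bm
    }
    clipped[[i]] <- image_volume(array(as.numeric(rm_), dim(bm)),
                                 brain_mask$spacing, brain_mask$origin)
    counts[i] <- sum(rm_)
    acc <- acc | rm_
  }
  out <- bm & !acc
  if (!any(out))
    warning("build_modified_mask: modified mask is empty", call. = FALSE)
  structure(list(mask = image_volume(array(as.numeric(out), dim(bm)),
                                     brain_mask$spacing, brain_mask$origin),
                 regions = clipped, region_voxels = counts,
                 brain_voxels = sum(bm)),
            class = "modified_mask")
}

#' Landmark/mask-assisted multimodal registration
#'
#' Stage 1 linearly registers the modified brain masks (by default their
#' Euclidean distance transforms under mean squared error, which gives the
#' mask alignment a wide capture range); stage 2 runs nonlinear
#' registration on two equally weighted channels — the image and its
#' modified mask — so the carved boundaries around misaligned structures
#' actively drive the deformation. The composed transform is returned.
#'
#' @param fixed,moving [image_volume]s.
#' @param fixed_mask,moving_mask [build_modified_mask()] results (or
#'   binary [image_volume]s).
#' @param spec optional [registration_spec()]; channel weights are forced
#'   equal.
#' @param mask_stage1 `"distance"` (default) registers distance
#'   transforms; `"raw"` uses the binary masks directly.
#' @return an [atlas_transform].
#' @export
landmark_assisted_register <- function(fixed, moving, fixed_mask,
                                       moving_mask, spec = NULL,
                                       mask_stage1 = c("distance", "raw")) {
  mask_stage1 <- match.arg(mask_stage1)
  fm <- if (inherits(fixed_mask, "modified_mask")) fixed_mask$mask else
    fixed_mask
  mm <- if (inherits(moving_mask, "modified_mask")) moving_mask$mask else
    moving_mask
  if (sum(fm$data > 0) == 0 || sum(mm$data > 0) == 0)
    stop("landmark_assisted_register: empty mask", call. = FALSE)
  # cross-modality image channel: mutual information, as in the initial
  # registration this stage refines
  if (is.null(spec)) spec <- registration_spec(metric = "mutual_information")
  # stage 1: linear on the masks only
  s1 <- spec
  s1$mode <- "linear"
  s1$metric <- "mean_squared_error"
  s1$channel_weights <- 1
  ch_f <- if (mask_stage1 == "distance") mask_distance(fm) else fm
  ch_m <- if (mask_stage1 == "distance") mask_distance(mm) else mm
  lin <- register(ch_f, ch_m, s1)
  # stage 2: nonlinear on (image, mask) with equal weights; the mask
  # channel enters as its smoothed (distance-like) form so the carved
  # boundaries exert force over a capture range, not just at the edge
  s2 <- spec
  s2$mode <- "nonlinear"
  s2$channel_weights <- c(0.5, 0.5)
  register(list(fixed, mask_distance(fm, sigma = 2)),
           list(moving, mask_distance(mm, sigma = 2)), s2, init = lin)
}

# smooth signed-ish distance surrogate: Gaussian-blurred mask contrast
mask_distance <- function(mask, sigma = 3) {
  g <- vol_grid(mask)
  sm <- cpp_gauss3d(as.numeric(mask$data > 0), as.integer(g$dim),
                    rep(sigma, 3))
  image_volume(array(sm, g$dim), g$spacing, g$origin)
}

#' Resample a warp once and apply it to several payloads
#'
#' The transform's displacement field is resampled to the target spacing a
#' single time, then applied to each payload; label payloads use nearest
#' interpolation.
#'
#' @param t an [atlas_transform].
#' @param target_spacing isotropic spacing (mm) for the resampled warp and
#'   outputs.
#' @param payloads list of [image_volume]s on the moving grid.
#' @param interpolation per-payload interpolation (recycled);
#'   `"nearest"` for labels.
#' @return list of transformed [image_volume]s on the resampled reference
#'   grid.
#' @export
resample_and_apply <- function(t, target_spacing, payloads,
                               interpolation = "linear") {
  stopifnot(is_transform(t), length(payloads) >= 1)
  interpolation <- rep_len(interpolation, length(payloads))
  g <- t$reference
  if (is.null(g)) stop("resample_and_apply: transform has no reference grid",
                       call. = FALSE)
  sp <- rep_len(as.numeric(target_spacing), 3)
  odim <- pmax(1L, as.integer(floor(grid_extent(g) / sp + 1e-9)) + 1L)
  g2 <- list(dim = odim, spacing = sp, origin = g$origin)
  t2 <- if (is.null(t$warp)) atlas_transform(t$affine, reference = g2) else
    atlas_transform(t$affine,
                    warp = array(resample_field(t$warp, g, g2),
                                 c(g2$dim, 3)),
                    inverse_warp = NULL, reference = g2)
  lapply(seq_along(payloads), function(i)
    apply_transform(payloads[[i]], t2, reference = g2,
                    interpolation = interpolation[i]))
}

#' Warp annotations back through a transform's inverse
#'
#' Given annotations in space A and the transform `t` that maps A-space
#' points into B (i.e. the result of registering B to A), applies the
#' inverse of `t` with nearest-neighbor interpolation to carry the label
#' volume into space B.
#'
#' @param annotations integer label [image_volume] (or
#'   [annotation_volume]) in space A.
#' @param t an [atlas_transform] (A fixed, B moving); must be invertible
#'   (affine, or warp with inverse available).
#' @param reference output grid (space B); defaults to the transform's
#'   reference grid.
#' @return the label volume in space B.
#' @export
backproject_annotations <- function(annotations, t, reference = NULL) {
  vol <- if (inherits(annotations, "annotation_volume"))
    annotations$labels else annotations
  if (!is.null(t$warp) && is.null(t$inverse_warp))
    stop("backproject_annotations: transform has no inverse warp",
         call. = FALSE)
  inv <- invert_transform(t)
  apply_transform(vol, inv, reference = reference,
                  interpolation = "nearest")
}

#' Stereotaxic coordinate frame from bregma and lambda
#'
#' Builds the rigid transform carrying template world coordinates into a
#' stereotaxic frame: bregma at the origin, the bregma-to-lambda direction
#' along the negative anterior-posterior (y) axis, dorsoventral axis
#' orthogonal in the sagittal plane. Rotation + translation only
#' (determinant +1, distances preserved); the dorsoventral zero sits at
#' the supplied bregma point.
#'
#' @param template an [image_volume] (postnatal template).
#' @param bregma,lambda world coordinates (mm), distinct.
#' @return a `stereotaxic_frame`: `transform` (an [atlas_transform]
#'   mapping stereotaxic points to template world), `rotation_deg`, and
#'   `template` resampled into the frame.
#' @export
to_stereotaxic <- function(template, bregma, lambda) {
  bregma <- as.numeric(bregma); lambda <- as.numeric(lambda)
  if (sqrt(sum((bregma - lambda)^2)) < 1e-9)
    stop("to_stereotaxic: bregma and lambda coincide", call. = FALSE)
  ap <- bregma - lambda              # lambda is caudal: +AP points rostral
  ap <- ap / sqrt(sum(ap^2))
  # build an orthonormal frame: ML stays as close to world x as possible
  ml <- c(1, 0, 0) - sum(c(1, 0, 0) * ap) * ap
  if (sqrt(sum(ml^2)) < 1e-6) ml <- c(0, 1, 0) - sum(c(0, 1, 0) * ap) * ap
  ml <- ml / sqrt(sum(ml^2))
  dv <- c(ap[2] * ml[3] - ap[3] * ml[2],
          ap[3] * ml[1] - ap[1] * ml[3],
          ap[1] * ml[2] - ap[2] * ml[1])
  dv <- dv / sqrt(sum(dv^2))
  R <- cbind(ml, ap, dv)             # columns: stereotaxic axes in world
  if (det(R) < 0) { dv <- -dv; R <- cbind(ml, ap, dv) }
  # stereotaxic -> world: p_w = R p_s + bregma
  A <- diag(4)
  A[1:3, 1:3] <- R
  A[1:3, 4] <- bregma
  t <- atlas_transform(A)
  ang <- acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
  g <- vol_grid(template)
  ext <- grid_extent(g)
  half <- sqrt(sum(ext^2)) / 2
  ctr_w <- g$origin + ext / 2
  ctr_s <- solve(R) %*% (ctr_w - bregma)
  odim <- as.integer(round(ext / g$spacing)) + 1L
  org <- as.numeric(ctr_s) - (odim - 1) * g$spacing / 2
  g2 <- list(dim = odim, spacing = g$spacing, origin = org)
  resampled <- apply_transform(template, t, reference = g2)
  structure(list(transform = t, rotation_deg = ang, bregma = bregma,
                 lambda = lambda, template = resampled),
            class = "stereotaxic_frame")
}

#' Dice overlap of two binary volumes
#' @param a,b binary [image_volume]s on one grid.
#' @export
dice_overlap <- function(a, b) {
  x <- a$data > 0; y <- b$data > 0
  2 * sum(x & y) / (sum(x) + sum(y))
}
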