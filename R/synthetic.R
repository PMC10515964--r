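#' Synthetic phantom brain
#'
#' Generates a smooth, ellipsoid-based phantom with an anatomy channel, an
#' optional spatially correlated "expression" channel and a binary brain
#' mask (the union of the structures). Structures default to a
#' mirror-symmetric arrangement about the x-center plane, so the default
#' phantom is exactly mirror symmetric when `asymmetry = 0` and
#' `noise_sigma = 0`. Every generator in this module is a pure function of
#' its arguments and `seed`.
#'
#' @param shape grid dimensions, length 3.
#' @param spacing voxel spacing in mm.
#' @param structures list of `list(center, radii, intensity, channel)` in
#'   voxel units (`channel` is `"anatomy"` or `"expression"`); NULL for the
#'   built-in brain-like arrangement.
#' @param asymmetry voxels by which one default structure pair is skewed in
#'   x, breaking mirror symmetry.
#' @param noise_sigma iid Gaussian noise sd added to the anatomy channel.
#' @param texture amplitude of a smooth, mirror-symmetric intensity
#'   texture modulating the anatomy inside the mask (gives flat interiors
#'   the local contrast real parenchyma has; 0 disables).
#' @param texture_sigma smoothing scale of the texture (voxels).
#' @param seed RNG seed.
#' @return list with elements `anatomy`, `expression`, `mask`
#'   ([image_volume]s), class `phantom`.
#' @export
make_phantom <- function(shape = c(64, 64, 64), spacing = c(1, 1, 1),
                         structures = NULL, asymmetry = 0,
                         noise_sigma = 0.02, texture = 0.2,
                         texture_sigma = 2, seed = 1) {
  shape <- as.integer(shape)
  if (is.null(structures)) structures <- default_structures(shape, asymmetry)
  for (s in structures)
    if (any(s$center - s$radii < 0) || any(s$center + s$radii > shape - 1))
      stop("make_phantom: structure outside grid", call. = FALSE)
  idx <- arrayInd(seq_len(prod(shape)), shape) - 1L
  anatomy <- numeric(prod(shape))
  expression <- numeric(prod(shape))
  mask <- logical(prod(shape))
  for (s in structures) {
    d2 <- ((idx[, 1] - s$center[1]) / s$radii[1])^2 +
          ((idx[, 2] - s$center[2]) / s$radii[2])^2 +
          ((idx[, 3] - s$center[3]) / s$radii[3])^2
    prof <- s$intensity * exp(-d2^2)          # soft-edged superellipsoid
    ch <- if (is.null(s$channel)) "anatomy" else s$channel
    if (ch == "expression") expression <- pmax(expression, prof)
    else anatomy <- pmax(anatomy, prof)
    mask <- mask | d2 <= 1
  }
  if (texture > 0) {
    tx <- with_seed(seed + 104729L,
                    array(stats::rnorm(prod(shape)), shape))
    tx <- array(cpp_gauss3d(as.numeric(tx), shape,
                            rep(texture_sigma, 3)), shape)
    tx <- tx / max(abs(tx))
    # symmetrize so textured phantoms stay mirror symmetric
    tx <- (tx + tx[shape[1]:1, , , drop = FALSE]) / 2
    anatomy <- anatomy * (1 + texture * as.numeric(tx)) * (anatomy > 0.05) +
      anatomy * (anatomy <= 0.05)
  }
  noise <- with_seed(seed, stats::rnorm(prod(shape), 0, noise_sigma))
  anat_v <- image_volume(array(anatomy + noise, shape), spacing)
  expr_v <- if (any(expression > 0))
    image_volume(array(expression, shape), spacing) else NULL
  mask_v <- image_volume(array(as.numeric(mask), shape), spacing)
  structure(list(anatomy = anat_v, expression = expr_v, mask = mask_v,
                 structures = structures, seed = seed),
            class = "phantom")
}

default_structures <- function(shape, asymmetry = 0) {
  c0 <- (shape - 1) / 2
  r0 <- shape * 0.38
  lat <- shape[1] * 0.16
  list(
    list(center = c0, radii = r0, intensity = 0.55, channel = "anatomy"),
    list(center = c0 + c(0, shape[2] * 0.12, shape[3] * 0.08),
         radii = shape * c(0.12, 0.16, 0.12), intensity = 0.95,
         channel = "anatomy"),
    list(center = c0 + c(lat + asymmetry, -shape[2] * 0.10, 0),
         radii = shape * 0.09, intensity = 0.85, channel = "anatomy"),
    list(center = c0 + c(-lat, -shape[2] * 0.10, 0),
         radii = shape * 0.09, intensity = 0.85, channel = "anatomy"),
    list(center = c0 + c(0, -shape[2] * 0.05, -shape[3] * 0.10),
         radii = shape * c(0.20, 0.10, 0.08), intensity = 0.75,
         channel = "expression"),
    list(center = c0 + c(0, shape[2] * 0.16, shape[3] * 0.10),
         radii = shape * c(0.10, 0.08, 0.08), intensity = 0.9,
         channel = "expression"))
}

# smooth random displacement field, returned in voxel units, c(dim, 3)
make_smooth_field <- function(dim, max_vox, seed, smooth_sigma = 8) {
  u <- with_seed(seed, array(stats::rnorm(prod(dim) * 3), c(dim, 3)))
  for (ax in 1:3)
    u[, , , ax] <- array(cpp_gauss3d(as.numeric(u[, , , ax]),
                                     as.integer(dim),
                                     rep(smooth_sigma, 3)), dim)
  mx <- max(sqrt(apply(u^2, 1:3, sum)))
  if (mx > 0) u <- u * (max_vox / mx)
  u
}

#' Synthetic deformed cohort
#'
#' Warps a phantom by `n` smooth random displacement fields with stated
#' maximum magnitude. Fields are mean-centered across the cohort, so the
#' cohort's mean shape is the phantom itself (up to the rescaling that
#' enforces the magnitude bound). The true subject-to-phantom fields are
#' returned for recovery scoring.
#'
#' @param phantom a `phantom` or [image_volume] (primary channel).
#' @param n cohort size, >= 2.
#' @param deform_magnitude maximum displacement in voxels.
#' @param seed RNG seed.
#' @param contrasts named list of functions applied to the primary channel
#'   intensities to derive sibling contrasts (default none).
#' @return list(cohort, true_transforms), where cohort is a [cohort()].
#' @export
make_cohort <- function(phantom, n, deform_magnitude = 3, seed = 1,
                        contrasts = NULL) {
  if (n < 2) stop("make_cohort: n must be >= 2", call. = FALSE)
  if (deform_magnitude < 0)
    stop("make_cohort: magnitude must be nonnegative", call. = FALSE)
  vol <- if (inherits(phantom, "phantom")) phantom$anatomy else phantom
  g <- vol_grid(vol)
  fields <- lapply(seq_len(n), function(i)
    make_smooth_field(g$dim, deform_magnitude, seed + 37L * i))
  mean_f <- Reduce(`+`, fields) / n
  fields <- lapply(fields, function(u) u - mean_f)
  mx <- max(vapply(fields, function(u) max(abs(u)), numeric(1)))
  if (mx > 0 && deform_magnitude > 0)
    fields <- lapply(fields, function(u) u * (deform_magnitude / mx))
  records <- vector("list", n)
  trues <- vector("list", n)
  for (i in seq_len(n)) {
    u_mm <- fields[[i]]
    for (ax in 1:3) u_mm[, , , ax] <- u_mm[, , , ax] * g$spacing[ax]
    t_i <- atlas_transform(diag(4), warp = u_mm,
                           inverse_warp = invert_field(u_mm, g),
                           reference = g)
    prim <- apply_transform(vol, t_i, reference = g)
    sib <- list()
    if (!is.null(contrasts))
      sib <- lapply(contrasts, function(f)
        image_volume(array(f(prim$data), g$dim), g$spacing, g$origin))
    records[[i]] <- subject_record(paste0("s", i), prim, sib)
    trues[[i]] <- t_i
  }
  list(cohort = cohort(records), true_transforms = trues)
}

#' Synthetic jittered tile grid
#'
#' Cuts a `cols x rows` grid of overlapping tiles out of a volume, applying
#' per-tile integer jitter, per-column z offsets and an optional per-tile
#' linear per-slice drift, and returns tiles with an instrumented chunked
#' reader plus the truth offset table. The anchor tile (column 1, row 1)
#' and column 1 carry no jitter or drift, so truth offsets are directly
#' comparable to stitching output anchored at the same tile.
#'
#' @param vol source [image_volume].
#' @param cols,rows grid size.
#' @param overlap nominal overlap fraction (>= 0.05).
#' @param jitter maximum absolute per-tile jitter in voxels (integer).
#' @param drift `"none"` or `"linear"` (per-slice xy drift ramping from 0
#'   to `drift_max` voxels over the stack along a per-tile direction).
#' @param drift_max drift magnitude in voxels.
#' @param seed RNG seed.
#' @param block_size chunk depth (slices) used by the instrumented reader.
#' @return list(grid = tile_grid, truth = per-tile list with per-slice
#'   integer offsets `dx`, `dy` and scalar `dz`).
#' @export
make_tile_stack <- function(vol, cols = 3, rows = 3, overlap = 0.15,
                            jitter = 5, drift = c("linear", "none"),
                            drift_max = 3, seed = 1, block_size = 32L) {
  drift <- match.arg(drift)
  if (overlap < 0.05) stop("make_tile_stack: overlap must be >= 0.05",
                           call. = FALSE)
  d <- dim(vol$data)
  Z <- d[3]
  margin <- as.integer(jitter +
                         if (drift == "none") 0L else ceiling(drift_max))
  tw <- floor((d[1] - 2 * margin) / (cols - (cols - 1) * overlap))
  th <- floor((d[2] - 2 * margin) / (rows - (rows - 1) * overlap))
  sx <- round(tw * (1 - overlap))
  sy <- round(th * (1 - overlap))
  margin_z <- jitter
  if (tw < 4 || th < 4 ||
      (cols - 1) * sx + tw + 2 * margin > d[1] ||
      (rows - 1) * sy + th + 2 * margin > d[2] ||
      2 * margin_z >= Z)
    stop("make_tile_stack: tiles exceed volume", call. = FALSE)
  zcount <- Z - 2 * margin_z
  tiles <- list()
  truth <- list()
  withr_state <- with_seed(seed, {
    dz_col <- c(0L, if (cols > 1)
      sample(seq(-jitter, jitter), cols - 1, replace = TRUE) else integer(0))
    out_t <- list(); out_tr <- list()
    for (r in seq_len(rows)) for (c in seq_len(cols)) {
      anchor <- (r == 1L && c == 1L)
      jx <- if (anchor) 0L else sample(seq(-jitter, jitter), 1)
      jy <- if (anchor) 0L else sample(seq(-jitter, jitter), 1)
      zs <- seq_len(zcount)
      if (drift == "linear" && !anchor) {
        th_t <- stats::runif(1, 0, 2 * pi)
        ramp <- drift_max * (zs - 1) / (zcount - 1)
        ddx <- as.integer(round(cos(th_t) * ramp))
        ddy <- as.integer(round(sin(th_t) * ramp))
      } else {
        ddx <- integer(zcount); ddy <- integer(zcount)
      }
      x0 <- margin + (c - 1L) * sx
      y0 <- margin + (r - 1L) * sy
      dzc <- dz_col[c]
      dat <- array(0, c(tw, th, zcount))
      for (z in zs) {
        xs <- x0 + jx + ddx[z] + seq_len(tw)
        ys <- y0 + jy + ddy[z] + seq_len(th)
        zsrc <- margin_z + z + dzc
        dat[, , z] <- vol$data[xs, ys, zsrc]
      }
      key <- sprintf("c%d_r%d", c, r)
      out_t[[key]] <- new_tile(dat, c, r, overlap, block_size)
      out_tr[[key]] <- list(col = c, row = r, dx = jx + ddx, dy = jy + ddy,
                            dz = dzc)
    }
    list(t = out_t, tr = out_tr)
  })
  grid <- tile_grid(withr_state$t, cols, rows, overlap,
                    spacing = vol$spacing, block_size = block_size)
  list(grid = grid, truth = withr_state$tr)
}

#' Synthetic sparse ISH slice series
#'
#' Samples 2-D sections from a phantom's expression channel along an axis,
#' intensity-inverts them (emulating dark chromogenic ISH signal on a
#' bright background), applies per-slice integer in-plane jitter, drops a
#' random fraction of interior slices and labels slices with interleaved
#' gene names. The truth (per-slice jitter, dropped indices, clean stack)
#' is returned for end-to-end scoring.
#'
#' @param expression [image_volume]; the signal channel being sectioned.
#' @param step slice sampling period in voxels along the slicing axis.
#' @param drop_fraction fraction of interior slices removed (0 to 0.5).
#' @param jitter_px maximum absolute in-plane jitter (integer pixels).
#' @param genes character vector cycled across slices (gene labels).
#' @param seed RNG seed.
#' @return list(series = slice_series, truth = list(jitter, dropped,
#'   clean)).
#' @export
make_ish_series <- function(expression, step = 2, drop_fraction = 0.2,
                            jitter_px = 4, genes = "geneA", seed = 1) {
  if (drop_fraction < 0 || drop_fraction > 0.5)
    stop("make_ish_series: drop_fraction must be in [0, 0.5]", call. = FALSE)
  d <- dim(expression$data)
  if (step >= d[3]) stop("make_ish_series: step larger than volume extent",
                         call. = FALSE)
  zidx <- seq(1L, d[3], by = step)
  nz <- length(zidx)
  rng <- range(expression$data)
  wid <- diff(rng); if (wid == 0) wid <- 1
  res <- with_seed(seed, {
    jit <- matrix(0L, nz, 2)
    if (jitter_px > 0 && nz > 2)
      jit[2:(nz - 1), ] <- matrix(sample(seq(-jitter_px, jitter_px),
                                         2 * (nz - 2), replace = TRUE),
                                  ncol = 2)
    ndrop <- floor(drop_fraction * nz)
    droppable <- setdiff(seq_len(nz), c(1L, nz))
    dropped <- if (ndrop > 0) sort(sample(droppable, ndrop)) else integer(0)
    list(jit = jit, dropped = dropped)
  })
  slices <- vector("list", nz)
  clean <- vector("list", nz)
  for (s in seq_len(nz)) {
    sl <- (expression$data[, , zidx[s]] - rng[1]) / wid
    clean[[s]] <- sl
    raw <- 1 - sl                      # bright background, dark signal
    slices[[s]] <- shift2d(raw, res$jit[s, 1], res$jit[s, 2], fill = 1)
  }
  present <- !(seq_len(nz) %in% res$dropped)
  z_mm <- expression$origin[3] + (zidx - 1) * expression$spacing[3]
  series <- slice_series(slices[present], z_positions = z_mm[present],
                         nominal_index = which(present),
                         n_nominal = nz,
                         gene = rep_len(genes, nz)[present],
                         pixel_spacing = expression$spacing[1:2])
  list(series = series,
       truth = list(jitter = res$jit, dropped = res$dropped,
                    z_index = zidx, clean = clean, z_mm = z_mm))
}

# integer 2-D shift with constant fill
shift2d <- function(m, dx, dy, fill = 0) {
  d <- dim(m)
  out <- matrix(fill, d[1], d[2])
  xs <- seq_len(d[1]) - dx
  ys <- seq_len(d[2]) - dy
  okx <- xs >= 1 & xs <= d[1]
  oky <- ys >= 1 & ys <= d[2]
  out[okx, oky] <- m[xs[okx], ys[oky]]
  out
}

#' Synthetic nested ontology and annotation volume
#'
#' Builds a `depth`-level ontology by recursive Voronoi-style partition of
#' an ellipsoidal brain mask: each node's children tile it exactly, so the
#' leaf-level annotation is mutually exclusive and exhaustive on the mask
#' by construction. `corrupt` seeds that many exhaustiveness violations
#' (in-mask voxels relabelled 0) for validator tests.
#'
#' @param depth tree depth below the root (>= 1).
#' @param branching children per node (>= 1).
#' @param shape annotation grid dimensions.
#' @param seed RNG seed.
#' @param corrupt number of in-mask voxels to zero out.
#' @return list(ontology, annotation ([annotation_volume]), mask).
#' @export
make_ontology_and_annotation <- function(depth = 2, branching = 3,
                                         shape = c(32, 32, 32), seed = 1,
                                         corrupt = 0) {
  if (depth < 1) stop("make_ontology_and_annotation: depth >= 1 required",
                      call. = FALSE)
  if (branching < 1) stop("make_ontology_and_annotation: branching >= 1",
                          call. = FALSE)
  shape <- as.integer(shape)
  idx <- arrayInd(seq_len(prod(shape)), shape) - 1L
  c0 <- (shape - 1) / 2
  mask <- (((idx[, 1] - c0[1]) / (shape[1] * 0.42))^2 +
           ((idx[, 2] - c0[2]) / (shape[2] * 0.42))^2 +
           ((idx[, 3] - c0[3]) / (shape[3] * 0.42))^2) <= 1
  rows <- list()
  labels <- integer(prod(shape))
  next_id <- 100L
  with_seed(seed, {
    assign_node <- function(vox, parent_id, level, name) {
      id <- next_id
      next_id <<- next_id + 1L
      rows[[length(rows) + 1L]] <<- data.frame(
        id16 = id, id32 = NA_integer_, name = name,
        acronym = paste0("R", id), parent_id16 = parent_id,
        color_hex = sprintf("#%06X", id * 9973L %% 16777216L),
        level = level, stringsAsFactors = FALSE)
      if (level == depth || length(vox) <= branching) {
        labels[vox] <<- id
        return(invisible(id))
      }
      seeds <- sample(vox, branching)
      sc <- idx[seeds, , drop = FALSE]
      vc <- idx[vox, , drop = FALSE]
      d2 <- vapply(seq_len(branching), function(b)
        (vc[, 1] - sc[b, 1])^2 + (vc[, 2] - sc[b, 2])^2 +
          (vc[, 3] - sc[b, 3])^2, numeric(length(vox)))
      nearest <- max.col(-d2, ties.method = "first")
      for (b in seq_len(branching))
        assign_node(vox[nearest == b], id, level + 1L,
                    paste0(name, ".", b))
      invisible(id)
    }
    assign_node(which(mask), NA_integer_, 0L, "root")
    if (corrupt > 0) {
      holes <- sample(which(mask), corrupt)
      labels[holes] <- 0L
    }
  })
  ont <- ontology(do.call(rbind, rows))
  mask_v <- image_volume(array(as.numeric(mask), shape), c(1, 1, 1))
  annot <- annotation_volume(image_volume(array(labels, shape), c(1, 1, 1)),
                             ont)
  list(ontology = ont, annotation = annot, mask = mask_v)
}

#' Two-phantom multimodal fixture with an internally displaced structure
#'
#' Emulates the failure mode mask-assisted registration targets: fixed and
#' moving phantoms share (approximately) their outer surface, but an
#' internal ellipsoid sits displaced in the moving phantom and carries
#' contrast only in the fixed modality, so intensity-driven registration
#' receives no signal to correct it. Modified masks carve the structure's
#' neighborhood out of each brain mask. Truth structure masks are returned
#' for centroid scoring.
#'
#' @param shape grid dimensions.
#' @param displacement structure displacement (voxels) in the moving
#'   phantom.
#' @param outer_scale,outer_shift mild outer-surface mismatch of the
#'   moving phantom (so whole-mask overlap is informative).
#' @param seed RNG seed.
#' @return list(fixed, moving, fixed_mask, moving_mask (modified masks),
#'   fixed_structure, moving_structure (truth masks)).
#' @export
make_multimodal_pair <- function(shape = c(48, 48, 48),
                                 displacement = c(6, 1, 0),
                                 outer_scale = 0.97,
                                 outer_shift = c(1, 0, 0), seed = 7) {
  shape <- as.integer(shape)
  c0 <- (shape - 1) / 2
  mkvol <- function(struct_center, struct_visible, scale, shift) {
    s <- list(
      list(center = c0 + shift, radii = shape * 0.40 * scale,
           intensity = 0.6, channel = "anatomy"),
      list(center = c0 + c(0, shape[2] * 0.2, 0) + shift,
           radii = shape * 0.10, intensity = 0.9, channel = "anatomy"))
    if (struct_visible)
      s <- c(s, list(list(center = struct_center, radii = shape * 0.09,
                          intensity = 1.2, channel = "anatomy")))
    make_phantom(shape, structures = s, noise_sigma = 0.01, texture = 0,
                 seed = seed)
  }
  ctr_f <- c0 + c(0, -shape[2] * 0.15, 0)
  ctr_m <- ctr_f + displacement
  fixed <- mkvol(ctr_f, TRUE, 1, c(0, 0, 0))
  moving <- mkvol(ctr_m, FALSE, outer_scale, outer_shift)
  idx <- arrayInd(seq_len(prod(shape)), shape) - 1L
  ball <- function(ctr, rfrac) image_volume(array(
    as.numeric(rowSums(sweep(idx, 2, ctr)^2) / (shape[1] * rfrac)^2 <= 1),
    shape))
  list(fixed = fixed$anatomy, moving = moving$anatomy,
       fixed_brain = fixed$mask, moving_brain = moving$mask,
       fixed_mask = build_modified_mask(fixed$mask, list(ball(ctr_f, 0.11))),
       moving_mask = build_modified_mask(moving$mask,
                                         list(ball(ctr_m, 0.11))),
       fixed_structure = ball(ctr_f, 0.09),
       moving_structure = ball(ctr_m, 0.09))
}
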