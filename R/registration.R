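#' Registration settings
#'
#' Bundles every tunable of the built-in engine. The engine runs a
#' multiresolution affine stage (Nelder-Mead over translation, then rigid,
#' then full 12-parameter affine) followed, in nonlinear modes, by
#' Gaussian-regularized demons updates. Mutual information uses a
#' `nbins`-bin joint histogram with Parzen-style smoothing; in the demons
#' stage cross-modality contrast is handled by remapping the moving image
#' through the conditional-mean intensity transfer estimated from that
#' histogram.
#'
#' @param mode `"linear"`, `"nonlinear"` or `"linear_then_nonlinear"`.
#' @param metric `"mutual_information"`, `"mean_squared_error"` or
#'   `"cross_correlation"`.
#' @param channel_weights nonnegative per-channel weights, at least one
#'   positive; recycled and renormalized to sum to 1.
#' @param levels multiresolution shrink factors, coarse to fine.
#' @param iterations demons iterations per level.
#' @param sigma_fluid,sigma_elastic Gaussian sigmas (voxels) smoothing the
#'   demons update and the accumulated field.
#' @param step demons step scale.
#' @param nbins joint-histogram bins for mutual information.
#' @param seed RNG seed recorded with the result (the built-in optimizers
#'   are deterministic; the seed covers any stochastic backend).
#' @return a `registration_spec` object.
#' @export
registration_spec <- function(mode = c("linear_then_nonlinear", "linear",
                                       "nonlinear"),
                              metric = c("mean_squared_error",
                                         "mutual_information",
                                         "cross_correlation"),
                              channel_weights = 1,
                              levels = c(4, 2, 1),
                              iterations = c(50, 30, 15),
                              sigma_fluid = 1, sigma_elastic = 1.5,
                              step = 1, nbins = 32L, seed = 0L) {
  mode <- match.arg(mode)
  metric <- match.arg(metric)
  if (any(channel_weights < 0) || !any(channel_weights > 0))
    stop("registration_spec: weights must be nonnegative, one positive",
         call. = FALSE)
  iterations <- rep_len(iterations, length(levels))
  structure(list(mode = mode, metric = metric,
                 channel_weights = channel_weights,
                 levels = levels, iterations = iterations,
                 sigma_fluid = sigma_fluid, sigma_elastic = sigma_elastic,
                 step = step, nbins = as.integer(nbins),
                 seed = as.integer(seed)),
            class = "registration_spec")
}

as_channel_list <- function(x) {
  if (is_image_volume(x)) list(x) else x
}

norm01 <- function(v) {
  r <- range(v$data)
  d <- if (diff(r) > 0) (v$data - r[1]) / diff(r) else v$data * 0
  image_volume(d, v$spacing, v$origin, v$orientation)
}

#' Similarity metric between two volumes on one grid
#'
#' Higher is better for `"mutual_information"` and `"cross_correlation"`;
#' lower is better for `"mean_squared_error"`. The returned
#' `score` attribute is always higher-is-better.
#'
#' @param fixed,moving [image_volume]s on the same grid.
#' @param metric metric name as in [registration_spec()].
#' @param nbins histogram bins for mutual information.
#' @export
metric_value <- function(fixed, moving, metric = "mean_squared_error",
                         nbins = 32L) {
  a <- as.numeric(fixed$data)
  b <- as.numeric(moving$data)
  v <- switch(metric,
    mean_squared_error = mean((a - b)^2),
    cross_correlation = ncc(a, b),
    mutual_information = {
      h <- cpp_joint_hist(a, b, nbins, min(a), max(a), min(b), max(b))
      h <- smooth_hist(h)
      p <- h / sum(h)
      px <- rowSums(p); py <- colSums(p)
      pp <- outer(px, py)
      nz <- p > 0
      sum(p[nz] * log(p[nz] / pp[nz]))
    },
    stop("unknown metric: ", metric, call. = FALSE))
  attr(v, "score") <- if (metric == "mean_squared_error") -v else v
  v
}

# Parzen-style smoothing of a joint histogram (small separable blur)
smooth_hist <- function(h, k = c(0.25, 0.5, 0.25)) {
  pad <- function(m) cbind(m[, 1], m, m[, ncol(m)])
  conv1 <- function(m) {
    m2 <- pad(m)
    k[1] * m2[, 1:ncol(m)] + k[2] * m2[, 2:(ncol(m) + 1)] +
      k[3] * m2[, 3:(ncol(m) + 2)]
  }
  t(conv1(t(conv1(h))))
}

channel_score <- function(fch, mch, w, metric, nbins) {
  s <- 0
  for (c in seq_along(fch))
    s <- s + w[c] * attr(metric_value(fch[[c]], mch[[c]], metric, nbins),
                         "score")
  s
}

# parameters: t(3), rot(3), log-scale(3), shear(3) -> 4x4 affine about center
params_to_affine <- function(p, center) {
  t3 <- p[1:3]; r <- p[4:6]; s <- exp(p[7:9]); sh <- p[10:12]
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  S <- diag(s)
  S[1, 2] <- sh[1]; S[1, 3] <- sh[2]; S[2, 3] <- sh[3]
  M <- Rz %*% Ry %*% Rx %*% S
  A <- diag(4)
  A[1:3, 1:3] <- M
  A[1:3, 4] <- t3 + center - M %*% center
  A
}

# Gaussian-smoothed downsampling of a channel list for one pyramid level
shrink_channels <- function(chans, shrink) {
  lapply(chans, function(v) {
    if (shrink <= 1) return(v)
    g <- vol_grid(v)
    sm <- cpp_gauss3d(as.numeric(v$data), as.integer(g$dim),
                      rep(shrink / 2, 3))
    resample_volume(image_volume(array(sm, g$dim), g$spacing, g$origin,
                                 v$orientation), g$spacing * shrink)
  })
}

check_channels <- function(fixed, moving) {
  if (length(fixed) == 0L || length(moving) == 0L)
    stop("register: empty channel list", call. = FALSE)
  if (length(fixed) != length(moving))
    stop("register: channel lists must have equal length", call. = FALSE)
  for (ch in c(fixed, moving))
    if (any(!is.finite(ch$data)))
      stop("register: non-finite voxels in input", call. = FALSE)
  for (ch in fixed[-1])
    if (!same_grid(ch, fixed[[1]]))
      stop("register: fixed channels on different grids", call. = FALSE)
  for (ch in moving[-1])
    if (!same_grid(ch, moving[[1]]))
      stop("register: moving channels on different grids", call. = FALSE)
}

#' Register a moving image (or channel list) to a fixed image
#'
#' The workhorse behind template construction, multimodal alignment and
#' slice-to-volume mapping. Returns the transform that, applied to
#' `moving` ([apply_transform]), resamples it onto the fixed grid in
#' register with `fixed`. The returned transform never scores worse than
#' the identity under the requested metric (the engine falls back to
#' identity otherwise), and nonlinear results carry a numerical inverse.
#'
#' @param fixed,moving [image_volume]s or equal-length lists of channels
#'   sharing each side's grid.
#' @param spec a [registration_spec()].
#' @param init optional initial [atlas_transform] (affine only).
#' @return an [atlas_transform] with attributes `metric` (final value) and
#'   `seed`.
#' @export
register <- function(fixed, moving, spec = registration_spec(),
                     init = NULL) {
  fixed <- as_channel_list(fixed)
  moving <- as_channel_list(moving)
  check_channels(fixed, moving)
  w <- rep_len(spec$channel_weights, length(fixed))
  w <- w / sum(w)
  fn <- lapply(fixed, norm01)
  mn <- lapply(moving, norm01)
  A <- if (is.null(init)) diag(4) else init$affine
  if (spec$mode %in% c("linear", "linear_then_nonlinear"))
    A <- affine_stage(fn, mn, w, spec, A)
  fg <- vol_grid(fixed[[1]])
  res <- if (spec$mode == "linear") {
    atlas_transform(A, reference = fg)
  } else {
    demons_stage(fn, mn, w, spec, A)
  }
  # metric monotonicity guard: never return worse than identity
  warp_all <- function(t) lapply(mn, apply_transform, t = t, reference = fg)
  s_res <- channel_score(fn, warp_all(res), w, spec$metric, spec$nbins)
  idt <- identity_transform(fg)
  s_id <- channel_score(fn, warp_all(idt), w, spec$metric, spec$nbins)
  if (s_res < s_id) {
    res <- idt
    s_res <- s_id
  }
  attr(res, "metric") <- s_res
  attr(res, "seed") <- spec$seed
  res
}

affine_stage <- function(fn, mn, w, spec, A0) {
  center <- colMeans(rbind(vol_grid(fn[[1]])$origin,
                           vol_grid(fn[[1]])$origin +
                             grid_extent(vol_grid(fn[[1]]))))
  p <- c(A0[1:3, 4] * 0, rep(0, 9))
  # seed translation from the affine init if given
  if (!is_identity_affine(A0)) p[1:3] <- A0[1:3, 4]
  # translation initialization by cross-correlation at the coarsest level
  sh0 <- max(spec$levels)
  fs <- shrink_channels(fn, sh0)
  ms <- shrink_channels(mn, sh0)
  if (all(dim(fs[[1]]$data) == dim(ms[[1]]$data)) &&
      spec$metric != "mutual_information" && is_identity_affine(A0)) {
    shv <- cross_correlate_shift(fs[[1]]$data, ms[[1]]$data)
    p[1:3] <- -shv * vol_grid(fs[[1]])$spacing
  }
  nlev <- length(spec$levels)
  for (li in seq_len(nlev)) {
    shrink <- spec$levels[li]
    # coarse levels fit translation (then rigid); the full 12-parameter
    # affine only at the finest level, where noise cannot masquerade as
    # rotation or shear
    blocks <- if (li == nlev) list(1:3, 4:6, 1:12)
      else if (li == 1L) list(1:3)
      else list(1:3, 4:6)
    fl <- shrink_channels(fn, shrink)
    ml <- shrink_channels(mn, shrink)
    gl <- vol_grid(fl[[1]])
    cost <- function(pb, active, base) {
      q <- base
      q[active] <- pb
      At <- params_to_affine(q, center)
      mw <- lapply(ml, function(mv) {
        sg <- vol_grid(mv)
        out <- cpp_warp(as.numeric(mv$data), as.integer(sg$dim), sg$spacing,
                        sg$origin, as.integer(gl$dim), gl$spacing,
                        gl$origin, At, NULL, 1L, 0)
        image_volume(array(out, gl$dim), gl$spacing, gl$origin)
      })
      -channel_score(fl, mw, w, spec$metric, spec$nbins)
    }
    for (blk in blocks) {
      sc <- ifelse(blk <= 3, max(gl$spacing), 0.05)
      opt <- stats::optim(p[blk], cost, active = blk, base = p,
                          method = "Nelder-Mead",
                          control = list(maxit = 250, reltol = 1e-8,
                                         parscale = sc))
      p[blk] <- opt$par
    }
  }
  params_to_affine(p, center)
}

# conditional-mean intensity transfer m -> E[f | bin(m)] for multimodal demons
intensity_transfer <- function(fvals, mvals, nbins) {
  h <- cpp_joint_hist(fvals, mvals, nbins, 0, 1, 0, 1)
  h <- smooth_hist(h)
  centers <- (seq_len(nbins) - 0.5) / nbins
  colsum <- colSums(h)
  cm <- as.numeric(t(h) %*% centers)
  cm[colsum > 0] <- cm[colsum > 0] / colsum[colsum > 0]
  cm[colsum == 0] <- centers[colsum == 0]
  function(v) {
    ib <- pmin(nbins, pmax(1L, 1L + as.integer(v * nbins)))
    cm[ib]
  }
}

demons_stage <- function(fn, mn, w, spec, A) {
  fg <- vol_grid(fn[[1]])
  u <- NULL
  multimodal <- spec$metric == "mutual_information"
  for (li in seq_along(spec$levels)) {
    shrink <- spec$levels[li]
    fl <- shrink_channels(fn, shrink)
    ml <- shrink_channels(mn, shrink)
    gl <- vol_grid(fl[[1]])
    n <- prod(gl$dim)
    u <- if (is.null(u)) array(0, c(gl$dim, 3)) else {
      prev <- attr(u, "grid")
      array(resample_field(u, prev, gl), c(gl$dim, 3))
    }
    kappa <- 1 / mean(gl$spacing)^2
    maxstep <- 1.0 * min(gl$spacing)
    mg <- vol_grid(ml[[1]])
    un <- cpp_demons_level(lapply(fl, function(v) as.numeric(v$data)),
                           lapply(ml, function(v) as.numeric(v$data)),
                           as.integer(gl$dim), gl$spacing, gl$origin,
                           as.integer(mg$dim), mg$spacing, mg$origin,
                           A, as.numeric(u), spec$iterations[li],
                           spec$sigma_fluid, spec$sigma_elastic,
                           spec$step, kappa, maxstep, w, multimodal,
                           spec$nbins)
    u <- array(un, c(gl$dim, 3))
    attr(u, "grid") <- gl
  }
  if (!all(dim(u)[1:3] == fg$dim))
    u <- array(resample_field(u, attr(u, "grid"), fg), c(fg$dim, 3))
  # fold the affine into the stored field? keep T(p) = A p + u(p): the demons
  # field was accumulated on top of A in exactly this convention already.
  uu <- u; attr(uu, "grid") <- NULL
  total <- total_displacement_on(atlas_transform(A, warp = uu,
                                                 reference = fg), fg)
  inv <- invert_field(total, fg)
  atlas_transform(A, warp = uu, inverse_warp = inv, reference = fg)
}
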