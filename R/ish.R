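#' Ordered 2-D slice series
#'
#' Container for sparse histological section series: an ordered list of
#' 2-D arrays with world z positions, the nominal slice index each present
#' slice occupies, and an optional per-slice gene label.
#'
#' @param slices list of 2-D numeric matrices, one per present slice.
#' @param z_positions strictly increasing world z (mm), one per slice.
#' @param nominal_index integer index of each slice in the full nominal
#'   stack (1-based).
#' @param n_nominal total number of nominal slice positions.
#' @param gene optional per-slice gene label.
#' @param pixel_spacing in-plane spacing (mm), length 2.
#' @return a `slice_series` object.
#' @export
slice_series <- function(slices, z_positions, nominal_index = NULL,
                         n_nominal = NULL, gene = NULL,
                         pixel_spacing = c(1, 1)) {
  if (length(slices) == 0) stop("slice_series: empty series", call. = FALSE)
  if (any(diff(z_positions) <= 0))
    stop("slice_series: z positions must be strictly increasing",
         call. = FALSE)
  stopifnot(length(z_positions) == length(slices))
  if (is.null(nominal_index)) nominal_index <- seq_along(slices)
  if (is.null(n_nominal)) n_nominal <- max(nominal_index)
  if (!is.null(gene)) stopifnot(length(gene) == length(slices))
  structure(list(slices = slices, z_positions = as.numeric(z_positions),
                 nominal_index = as.integer(nominal_index),
                 n_nominal = as.integer(n_nominal), gene = gene,
                 pixel_spacing = rep_len(as.numeric(pixel_spacing), 2)),
            class = "slice_series")
}

#' @export
length.slice_series <- function(x) length(x$slices)

#' @export
print.slice_series <- function(x, ...) {
  cat(sprintf("<slice_series> %d of %d nominal slices, %s px, genes: %s\n",
              length(x), x$n_nominal,
              paste(dim(x$slices[[1]]), collapse = "x"),
              if (is.null(x$gene)) "-" else
                paste(unique(x$gene), collapse = ", ")))
  invisible(x)
}

present_mask <- function(series) {
  m <- logical(series$n_nominal)
  m[series$nominal_index] <- TRUE
  m
}

#' Preprocess raw ISH slices
#'
#' Rescales each slice to the unit intensity range, intensity-inverts it (chromogenic ISH is
#' dark-on-bright; downstream processing wants bright signal) and
#' resamples to `size x size` pixels, preserving aspect ratio by centered
#' zero padding.
#'
#' @param raw a [slice_series()] of grayscale slices.
#' @param size target edge length in pixels (default 512).
#' @return a [slice_series()] of inverted `size x size` slices.
#' @export
preprocess_slices <- function(raw, size = 512L) {
  stopifnot(inherits(raw, "slice_series"))
  # one intensity scale for the whole series (slices of one subject share
  # their staining scale; a per-slice rescale would blow up empty slices)
  r <- range(unlist(lapply(raw$slices, range)))
  out <- lapply(raw$slices, function(sl) {
    v <- if (diff(r) > 0) (sl - r[1]) / diff(r) else sl * 0
    v <- 1 - v
    d <- dim(v)
    if (all(d == size)) return(v)
    s <- size / max(d)
    nd <- pmax(1L, as.integer(round(d * s)))
    g <- list(dim = c(d, 1L), spacing = c(1, 1, 1), origin = c(0, 0, 0))
    res <- cpp_warp(as.numeric(v), as.integer(g$dim), g$spacing, g$origin,
                    as.integer(c(nd, 1L)), c(d[1] / nd[1], d[2] / nd[2], 1),
                    c(0, 0, 0), diag(4), NULL, 1L, 0)
    m <- matrix(res, nd[1], nd[2])
    pad <- matrix(0, size, size)
    off <- (size - nd) %/% 2L
    pad[off[1] + seq_len(nd[1]), off[2] + seq_len(nd[2])] <- m
    pad
  })
  sc <- max(dim(raw$slices[[1]])) / size
  slice_series(out, raw$z_positions, raw$nominal_index, raw$n_nominal,
               raw$gene, pixel_spacing = raw$pixel_spacing * sc)
}

# full nominal z positions by linear index->z fit through present slices
nominal_z <- function(series) {
  idx <- series$nominal_index
  if (length(idx) == 1L) return(series$z_positions)
  co <- stats::coef(stats::lm(series$z_positions ~ idx))
  co[1] + co[2] * seq_len(series$n_nominal)
}

#' Reconstruct a sparse slice series into a 3-D volume
#'
#' Stacks the present slices at their nominal positions and generates the
#' missing slices by fitting, per pixel column, an interpolating spline
#' along z through the present slices (the separable reading of
#' scattered-data B-spline infill for this slice-wise sampling pattern:
#' the data are dense in-plane and scattered only along z). Present slices
#' are stored verbatim — reconstruction never alters measured data.
#' Cubic order reproduces any intensity profile linear in z exactly.
#'
#' @param sparse a [slice_series()] (already preprocessed).
#' @param order spline order along z: 3 (natural cubic) or 1 (linear).
#' @param mesh reserved for coarser control meshes; NULL fits an
#'   interpolating spline.
#' @return a `sparse_reconstruction`: `volume` ([image_volume]),
#'   `provenance` data frame (slice, source, gene), `series`.
#' @export
bspline_fill <- function(sparse, order = 3L, mesh = NULL) {
  stopifnot(inherits(sparse, "slice_series"))
  np <- length(sparse)
  if (np < 2) stop("bspline_fill: need at least 2 present slices",
                   call. = FALSE)
  d2 <- dim(sparse$slices[[1]])
  nz <- sparse$n_nominal
  zfull <- nominal_z(sparse)
  zp <- sparse$z_positions
  vol <- array(0, c(d2, nz))
  for (s in seq_len(np)) vol[, , sparse$nominal_index[s]] <-
    sparse$slices[[s]]
  missing <- setdiff(seq_len(nz), sparse$nominal_index)
  if (length(missing) > 0) {
    # common z knots for every pixel column: build the basis-weight matrix
    # once (value at missing z = linear combination of present slices)
    W <- vapply(seq_len(np), function(j) {
      e <- numeric(np); e[j] <- 1
      if (order >= 3L) {
        f <- stats::splinefun(zp, e, method = "natural")
        f(zfull[missing])
      } else {
        stats::approx(zp, e, xout = zfull[missing], rule = 2)$y
      }
    }, numeric(length(missing)))
    W <- matrix(W, nrow = length(missing))
    P <- matrix(unlist(sparse$slices, use.names = FALSE), prod(d2), np)
    Fm <- P %*% t(W)
    for (mi in seq_along(missing)) vol[, , missing[mi]] <- Fm[, mi]
  }
  dz <- if (nz > 1) mean(diff(zfull)) else 1
  v <- image_volume(vol, spacing = c(sparse$pixel_spacing, dz),
                    origin = c(0, 0, zfull[1]))
  prov <- data.frame(
    slice = seq_len(nz),
    source = ifelse(seq_len(nz) %in% sparse$nominal_index, "original",
                    "interpolated"),
    gene = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(sparse$gene))
    prov$gene[sparse$nominal_index] <- sparse$gene
  structure(list(volume = v, provenance = prov, series = sparse,
                 fill = if (order >= 3L) "cubic" else "linear"),
            class = "sparse_reconstruction")
}

#' @export
print.sparse_reconstruction <- function(x, ...) {
  cat(sprintf("<sparse_reconstruction> %s, %d original / %d interpolated slices (%s fill)\n",
              paste(dim(x$volume$data), collapse = "x"),
              sum(x$provenance$source == "original"),
              sum(x$provenance$source == "interpolated"), x$fill))
  invisible(x)
}

#' Linear alignment of a template to a reconstruction
#'
#' Registers the template to the reconstruction with a linear transform
#' and returns the template resampled onto the reconstruction grid — the
#' per-slice reference for [slicewise_refine()].
#'
#' @param recon a `sparse_reconstruction`.
#' @param template an [image_volume].
#' @param spec optional [registration_spec()] (mode forced linear).
#' @return list(reference = warped template, transform).
#' @export
align_reference_linear <- function(recon, template, spec = NULL) {
  if (is.null(spec)) spec <- registration_spec()
  spec$mode <- "linear"
  t <- register(recon$volume, template, spec)
  list(reference = apply_transform(template, t,
                                   reference = vol_grid(recon$volume)),
       transform = t)
}

#' Slice-wise in-plane refinement against an aligned reference
#'
#' Registers every original slice independently, in 2-D, to the
#' corresponding slice of the linearly aligned reference (integer
#' translation search maximizing the chosen metric, with parabolic
#' sub-pixel refinement), then regenerates the interpolated slices from
#' the refined originals. Improves within-subject consistency (adjacent
#' slice correlation) on jittered series.
#'
#' @param recon a `sparse_reconstruction`.
#' @param reference an [image_volume] on the reconstruction grid (see
#'   [align_reference_linear()]).
#' @param metric metric for the slice search (default mutual
#'   information).
#' @param search maximum |shift| in pixels.
#' @return the refined `sparse_reconstruction`; per-slice shifts in
#'   `$slice_shifts`.
#' @export
slicewise_refine <- function(recon, reference,
                             metric = "mutual_information", search = 6L) {
  stopifnot(inherits(recon, "sparse_reconstruction"))
  if (!all(dim(reference$data) == dim(recon$volume$data)))
    stop("slicewise_refine: reference grid mismatch", call. = FALSE)
  ser <- recon$series
  shifts <- matrix(0, length(ser), 2)
  newsl <- ser$slices
  for (s in seq_along(ser$slices)) {
    ref2 <- reference$data[, , ser$nominal_index[s]]
    if (stats::sd(ref2) == 0) next
    sl <- ser$slices[[s]]
    # shifts expose the border; fill with the slice's own background level
    bg <- stats::median(c(sl[1, ], sl[nrow(sl), ], sl[, 1], sl[, ncol(sl)]))
    sh <- slice_shift_search(ref2, sl, metric, search, fill = bg)
    shifts[s, ] <- sh
    newsl[[s]] <- shift2d(sl, round(sh[1]), round(sh[2]), fill = bg)
  }
  ser2 <- slice_series(newsl, ser$z_positions, ser$nominal_index,
                       ser$n_nominal, ser$gene, ser$pixel_spacing)
  out <- bspline_fill(ser2, order = if (recon$fill == "cubic") 3L else 1L)
  out$slice_shifts <- shifts
  out
}

# integer shift search maximizing a similarity metric, ties toward zero
slice_shift_search <- function(ref, mov, metric, search, fill = 0) {
  best <- -Inf; bs <- c(0L, 0L)
  mkvol <- function(m) image_volume(array(m, c(dim(m), 1L)))
  rv <- mkvol(ref)
  for (dx in -search:search) for (dy in -search:search) {
    mv <- shift2d(mov, dx, dy, fill = fill)
    sc <- attr(metric_value(rv, mkvol(mv), metric), "score")
    if (sc > best + 1e-12 ||
        (sc > best - 1e-12 && sum(abs(c(dx, dy))) < sum(abs(bs)))) {
      best <- sc; bs <- c(dx, dy)
    }
  }
  bs
}

#' Map a reconstruction into template space
#'
#' Registers the template to the (slice-wise corrected) reconstruction —
#' linear then nonlinear — and applies the inverse transform to carry the
#' reconstruction onto the template grid.
#'
#' @param recon a `sparse_reconstruction`.
#' @param template an [image_volume].
#' @param spec a [registration_spec()].
#' @param init optional linear initialization (from
#'   [align_reference_linear()]).
#' @return list(transform = template-to-reconstruction transform,
#'   mapped = reconstruction on the template grid).
#' @export
map_to_template <- function(recon, template, spec = registration_spec(),
                            init = NULL) {
  stopifnot(inherits(recon, "sparse_reconstruction"))
  t <- register(recon$volume, template, spec, init = init)
  inv <- invert_transform(t)
  mapped <- apply_transform(recon$volume, inv,
                            reference = vol_grid(template))
  list(transform = t, mapped = mapped)
}

#' Split a multi-gene reconstruction into per-gene template volumes
#'
#' Divides the refined series by gene label, re-fills each single-gene
#' series along z, and warps each through the supplied
#' template-to-reconstruction transform's inverse. Genes with fewer than
#' two slices are skipped with a warning.
#'
#' @param recon a `sparse_reconstruction` whose series carries gene
#'   labels.
#' @param transform the transform from [map_to_template()].
#' @param template the template [image_volume] (output grid).
#' @return named list of per-gene [image_volume]s; each carries a
#'   `provenance` attribute naming its source slices.
#' @export
split_genes <- function(recon, transform, template) {
  ser <- recon$series
  if (is.null(ser$gene))
    stop("split_genes: series has no gene labels", call. = FALSE)
  inv <- invert_transform(transform)
  out <- list()
  for (gn in unique(ser$gene)) {
    keep <- which(ser$gene == gn)
    if (length(keep) < 2L) {
      warning("split_genes: gene ", gn, " has < 2 slices; skipped",
              call. = FALSE)
      next
    }
    sub <- slice_series(ser$slices[keep], ser$z_positions[keep],
                        ser$nominal_index[keep], ser$n_nominal,
                        rep(gn, length(keep)), ser$pixel_spacing)
    rec_g <- bspline_fill(sub, order = if (recon$fill == "cubic") 3L else 1L)
    mapped <- apply_transform(rec_g$volume, inv,
                              reference = vol_grid(template))
    attr(mapped, "provenance") <- rec_g$provenance
    out[[gn]] <- mapped
  }
  out
}

#' Full 2-D ISH to 3-D template mapping chain
#'
#' Runs the seven-step chain: preprocess (invert + resize), reconstruct
#' with spline infill, linear template alignment, slice-wise refinement,
#' nonlinear template registration, inverse mapping to the template, and
#' per-gene splitting.
#'
#' @param raw a [slice_series()] of raw ISH sections.
#' @param template target [image_volume].
#' @param size working in-plane resolution (pixels).
#' @param spec [registration_spec()] for the volume registrations.
#' @param slice_metric metric for the slice-wise search.
#' @return list(recon, refined, mapped, transform, genes).
#' @export
ish_map <- function(raw, template, size = 512L,
                    spec = registration_spec(), slice_metric = NULL) {
  if (is.null(slice_metric))
    slice_metric <- if (spec$metric == "mean_squared_error")
      "cross_correlation" else spec$metric
  pre <- preprocess_slices(raw, size = size)
  recon <- bspline_fill(pre)
  ali <- align_reference_linear(recon, template, spec)
  refined <- slicewise_refine(recon, ali$reference, metric = slice_metric)
  mt <- map_to_template(refined, template, spec, init = ali$transform)
  genes <- if (!is.null(pre$gene))
    split_genes(refined, mt$transform, template) else list()
  list(recon = recon, refined = refined, mapped = mt$mapped,
       transform = mt$transform, genes = genes)
}
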