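#' Dense 3-D image volume
#'
#' The basic container used throughout the toolkit: a rank-3 numeric array
#' with voxel spacing, world origin and an axis-orientation code. Grids are
#' node-centered: the world coordinate of 0-based voxel index `i` is
#' `origin + i * spacing`. The internal unit is always mm; volumes tagged
#' `"um"` are converted on construction and the tag is kept so they can be
#' written back in their source unit.
#'
#' @param data numeric rank-3 array.
#' @param spacing per-axis voxel size, length 3, strictly positive.
#' @param origin world position of voxel (0,0,0), length 3.
#' @param orientation three-letter axis code; the toolkit's canonical
#'   internal orientation is `"RAS"` (left-right, posterior-anterior,
#'   inferior-superior).
#' @param unit `"mm"` or `"um"`; `"um"` inputs are converted to mm.
#' @return an `image_volume` object.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         orientation = "RAS", unit = "mm") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("image_volume: `data` must be a rank-3 array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("image_volume: spacing must be 3 strictly positive numbers",
         call. = FALSE)
  unit <- match.arg(unit, c("mm", "um"))
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("image_volume: origin must have length 3",
                                 call. = FALSE)
  if (unit == "um") {
    spacing <- spacing * 1e-3
    origin <- origin * 1e-3
  }
  if (!is.character(orientation) || nchar(orientation) != 3L)
    stop("image_volume: orientation must be a 3-letter code", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin,
                 orientation = toupper(orientation), unit = unit),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %s mm, origin %s, %s\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = " x "),
              paste(signif(x$origin, 4), collapse = ", "),
              x$orientation))
  cat(sprintf("  intensity range [%g, %g]%s\n",
              min(x$data), max(x$data),
              if (x$unit == "um") ", source unit um" else ""))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' @export
as.array.image_volume <- function(x, ...) x$data

is_image_volume <- function(x) inherits(x, "image_volume")

# grid descriptor shared by transforms and resampling
vol_grid <- function(vol) {
  list(dim = dim(vol$data), spacing = vol$spacing, origin = vol$origin)
}

grids_equal <- function(a, b, tol = 1e-8) {
  all(a$dim == b$dim) && all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

same_grid <- function(a, b) grids_equal(vol_grid(a), vol_grid(b))

# world extent (node-centered: first to last voxel center)
grid_extent <- function(g) (g$dim - 1) * g$spacing

interp_code <- function(interpolation) {
  switch(match.arg(interpolation, c("linear", "nearest", "bspline")),
         nearest = 0L, linear = 1L, bspline = 3L)
}

#' Load a volume from disk
#'
#' Reads NIfTI-1 (`.nii`, `.nii.gz`) or multi-page TIFF (`.tif`, `.tiff`)
#' files into an [image_volume]. NIfTI spacing and origin are taken from the
#' header (pixdim / qform, mm). TIFF has no calibrated spacing: unless a
#' JSON sidecar `<path>.json` with `spacing`/`origin`/`unit` fields exists,
#' spacing 1 mm is assumed and a warning is emitted. The distributed files'
#' orientation convention is not guessable from a bare array, so an
#' `orientation` override is exposed rather than inferred.
#'
#' @param path file path.
#' @param format optional hint, `"nifti"` or `"tiff"`; default from the
#'   extension.
#' @param orientation orientation code to stamp on the result (default RAS).
#' @return an [image_volume].
#' @export
load_volume <- function(path, format = NULL, orientation = "RAS") {
  if (!file.exists(path)) stop("load_volume: no such file: ", path,
                               call. = FALSE)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext, nii = "nifti", tif = , tiff = "tiff",
                     stop("load_volume: unsupported extension: ", ext,
                          call. = FALSE))
  }
  format <- match.arg(format, c("nifti", "tiff"))
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    data <- as.array(img)
    data <- array(as.numeric(data), dim(data))
    if (length(dim(data)) != 3L)
      stop("load_volume: expected a rank-3 volume, got rank ",
           length(dim(data)), call. = FALSE)
    sp <- RNifti::pixdim(img)[1:3]
    xf <- try(RNifti::xform(img), silent = TRUE)
    org <- if (inherits(xf, "try-error")) c(0, 0, 0) else
      as.numeric(xf[1:3, 4])
    # qform handedness is not interpreted; the caller asserts orientation
    vol <- image_volume(data, spacing = abs(sp), origin = org,
                        orientation = orientation)
    side <- paste0(path, ".json")
    if (file.exists(side)) vol <- apply_sidecar(vol, side)
    vol
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) {
      if (length(dim(p)) == 3L) p <- p[, , 1] # drop extra channels
      # readTIFF returns row-major matrices (rows = y); transpose to x,y
      t(p)
    })
    d2 <- dim(pages[[1]])
    if (is.null(d2) || length(d2) != 2L)
      stop("load_volume: TIFF pages must be 2-D", call. = FALSE)
    data <- array(unlist(pages, use.names = FALSE), c(d2, length(pages)))
    side <- paste0(path, ".json")
    if (file.exists(side)) {
      apply_sidecar(image_volume(data, orientation = orientation), side)
    } else {
      warning("load_volume: TIFF has no spacing metadata; assuming 1 mm",
              call. = FALSE)
      image_volume(data, spacing = c(1, 1, 1), orientation = orientation)
    }
  }
}

apply_sidecar <- function(vol, side) {
  meta <- jsonlite::fromJSON(side)
  if (!is.null(meta$range)) {
    rng <- as.numeric(meta$range)
    sc <- if (diff(rng) > 0) diff(rng) else 1
    vol$data <- vol$data * sc + rng[1]
  }
  unit <- if (!is.null(meta$unit)) meta$unit else "mm"
  sp <- if (!is.null(meta$spacing)) as.numeric(meta$spacing) else
    vol$spacing
  org <- if (!is.null(meta$origin)) as.numeric(meta$origin) else vol$origin
  orient <- if (!is.null(meta$orientation)) meta$orientation else
    vol$orientation
  if (identical(unit, "um")) {
    # image_volume() will scale back down; hand over source-unit values
    image_volume(vol$data, spacing = sp, origin = org, orientation = orient,
                 unit = "um")
  } else {
    image_volume(vol$data, spacing = sp, origin = org, orientation = orient)
  }
}

#' Save a volume to disk
#'
#' NIfTI output stores spacing and origin in the header (mm). TIFF output
#' writes one 32-bit float page per z slice plus a JSON sidecar
#' `<path>.json` holding spacing, origin, orientation and source unit, so
#' that `load_volume(save_volume(v))` round-trips within float32 precision.
#'
#' @param vol an [image_volume].
#' @param path output path; extension selects the format.
#' @return `path`, invisibly.
#' @export
save_volume <- function(vol, path) {
  stopifnot(is_image_volume(vol))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("save_volume: no such directory: ", dir,
                             call. = FALSE)
  if (file.access(dir, 2) != 0)
    stop("save_volume: directory not writable: ", dir, call. = FALSE)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    img <- RNifti::asNifti(vol$data)
    RNifti::pixdim(img) <- vol$spacing
    m <- diag(c(vol$spacing, 1))
    m[1:3, 4] <- vol$origin
    img <- RNifti::`qform<-`(img, structure(m, code = 2L))
    RNifti::writeNifti(img, path)
    if (vol$unit == "um")
      jsonlite::write_json(list(unit = "um", orientation = vol$orientation),
                           paste0(path, ".json"), auto_unbox = TRUE)
  } else if (ext %in% c("tif", "tiff")) {
    # TIFF float storage is defined for [0, 1]; rescale and record the
    # range in the sidecar so loading restores original intensities
    rng <- range(vol$data)
    sc <- if (diff(rng) > 0) diff(rng) else 1
    pages <- lapply(seq_len(dim(vol$data)[3]),
                    function(k) t((vol$data[, , k] - rng[1]) / sc))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    meta <- list(spacing = vol$spacing, origin = vol$origin,
                 orientation = vol$orientation, unit = "mm",
                 range = rng)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else {
    stop("save_volume: unsupported extension: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' Resample a volume to a new voxel spacing
#'
#' The world extent is preserved within one target voxel; the origin is
#' kept. `"nearest"` never invents label values and is the required mode
#' for label volumes. `"sum"` aggregates integer-factor blocks (each output
#' voxel is the sum of its source block), the mode used to carry
#' classified-voxel counts across resolutions.
#'
#' @param vol an [image_volume].
#' @param target_spacing per-axis new spacing (mm); scalar is recycled.
#' @param interpolation `"linear"`, `"nearest"`, `"bspline"` or `"sum"`.
#' @return an [image_volume] on the new grid.
#' @export
resample_volume <- function(vol, target_spacing,
                            interpolation = c("linear", "nearest",
                                              "bspline", "sum")) {
  stopifnot(is_image_volume(vol))
  interpolation <- match.arg(interpolation)
  sp <- as.numeric(target_spacing)
  if (length(sp) == 1L) sp <- rep(sp, 3L)
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("resample_volume: target spacing must be positive", call. = FALSE)
  g <- vol_grid(vol)
  if (interpolation == "sum") {
    f <- sp / g$spacing
    fi <- as.integer(round(f))
    if (any(abs(f - fi) > 1e-6) || any(fi < 1))
      stop("resample_volume: sum mode needs integer downsampling factors",
           call. = FALSE)
    out <- cpp_block_sum(as.numeric(vol$data), as.integer(g$dim), fi)
    return(image_volume(array(out, dim(out)), spacing = g$spacing * fi,
                        origin = g$origin + (fi - 1) * g$spacing / 2,
                        orientation = vol$orientation))
  }
  if (all(abs(sp - g$spacing) < 1e-12)) return(vol)
  odim <- pmax(1L, as.integer(floor(grid_extent(g) / sp + 1e-9)) + 1L)
  out <- cpp_warp(as.numeric(vol$data), as.integer(g$dim), g$spacing,
                  g$origin, odim, sp, g$origin, diag(4), NULL,
                  interp_code(interpolation), 0)
  image_volume(array(out, odim), spacing = sp, origin = g$origin,
               orientation = vol$orientation)
}

# sample a volume at arbitrary world points (n x 3 matrix) -> values
sample_at_points <- function(vol, pts, interpolation = "linear") {
  g <- vol_grid(vol)
  ci <- sweep(sweep(pts, 2, g$origin), 2, g$spacing, "/")
  if (interpolation == "nearest") {
    idx <- round(ci)
    ok <- idx[, 1] >= 0 & idx[, 2] >= 0 & idx[, 3] >= 0 &
      idx[, 1] < g$dim[1] & idx[, 2] < g$dim[2] & idx[, 3] < g$dim[3]
    v <- numeric(nrow(pts))
    lin <- 1 + idx[ok, 1] + g$dim[1] * (idx[ok, 2] + g$dim[2] * idx[ok, 3])
    v[ok] <- as.numeric(vol$data)[lin]
    v
  } else {
    vapply(seq_len(nrow(pts)), function(r) {
      as.numeric(cpp_warp(as.numeric(vol$data), as.integer(g$dim), g$spacing,
                          g$origin, c(1L, 1L, 1L), c(1, 1, 1), pts[r, ],
                          diag(4), NULL, 1L, 0))
    }, numeric(1))
  }
}
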