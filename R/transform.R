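#' Spatial transform (affine + optional dense displacement field)
#'
#' A transform maps points of a fixed/reference space into the moving
#' space (pull-back convention): `T(p) = A %*% p + u(p)`, with `A` a 4x4
#' world-coordinate affine and `u` an optional dense displacement field in
#' mm defined on the reference grid. Applying a transform to a volume
#' samples the volume at `T(p)` for every reference voxel `p`, so
#' registration of `moving` to `fixed` yields the transform whose
#' application warps `moving` onto the fixed grid. When a nonlinear warp is
#' present its numerical inverse is carried alongside.
#'
#' @param affine 4x4 matrix (world mm), last row (0,0,0,1).
#' @param warp displacement array `c(dim, 3)` in mm on `reference`, or NULL.
#' @param inverse_warp like `warp`, for the inverse map, or NULL.
#' @param reference grid descriptor: list(dim, spacing, origin).
#' @return an `atlas_transform` object.
#' @export
atlas_transform <- function(affine = diag(4), warp = NULL,
                            inverse_warp = NULL, reference = NULL) {
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4, 4)))
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("atlas_transform: affine is singular", call. = FALSE)
  if (!is.null(warp) && is.null(reference))
    stop("atlas_transform: a warp needs a reference grid", call. = FALSE)
  structure(list(affine = affine, warp = warp, inverse_warp = inverse_warp,
                 reference = reference),
            class = "atlas_transform")
}

#' @export
print.atlas_transform <- function(x, ...) {
  cat("<atlas_transform>\n  affine translation:",
      paste(signif(x$affine[1:3, 4], 4), collapse = ", "), "mm\n")
  if (!is.null(x$warp))
    cat(sprintf("  warp on %s grid, max |u| = %.4g mm\n",
                paste(x$reference$dim, collapse = "x"),
                max(abs(x$warp))))
  invisible(x)
}

is_transform <- function(x) inherits(x, "atlas_transform")

identity_transform <- function(reference = NULL)
  atlas_transform(diag(4), reference = reference)

translation_transform <- function(t) {
  A <- diag(4); A[1:3, 4] <- t
  atlas_transform(A)
}

is_identity_affine <- function(A, tol = 1e-12) max(abs(A - diag(4))) < tol

# evaluate the point map T(p) for an n x 3 matrix of world points
map_points <- function(t, pts) {
  q <- cbind(pts, 1) %*% t(t$affine)
  q <- q[, 1:3, drop = FALSE]
  if (!is.null(t$warp)) {
    g <- t$reference
    n <- prod(g$dim)
    for (ax in 1:3) {
      comp <- image_volume(array(t$warp[seq_len(n) + (ax - 1) * n], g$dim),
                           g$spacing, g$origin)
      q[, ax] <- q[, ax] + sample_at_points(comp, pts)
    }
  }
  q
}

# total displacement of T sampled on grid g (mm): T(p) - p
total_displacement_on <- function(t, g) {
  pts_disp <- array(0, c(g$dim, 3))
  n <- prod(g$dim)
  # affine part evaluated analytically on the grid
  idx <- arrayInd(seq_len(n), g$dim) - 1L
  p <- sweep(sweep(idx, 2, g$spacing, "*"), 2, g$origin, "+")
  q <- cbind(p, 1) %*% t(t$affine)
  u <- q[, 1:3, drop = FALSE] - p
  if (!is.null(t$warp)) {
    wg <- t$reference
    if (grids_equal(wg, g)) {
      u <- u + matrix(t$warp, n, 3)
    } else {
      for (ax in 1:3) {
        comp <- image_volume(array(t$warp[seq_len(prod(wg$dim)) +
                                            (ax - 1) * prod(wg$dim)],
                                   wg$dim), wg$spacing, wg$origin)
        u[, ax] <- u[, ax] + as.numeric(
          cpp_warp(as.numeric(comp$data), as.integer(wg$dim), wg$spacing,
                   wg$origin, as.integer(g$dim), g$spacing, g$origin,
                   diag(4), NULL, 2L, 0))
      }
    }
  }
  pts_disp[] <- u
  pts_disp
}

#' Apply a transform to a volume
#'
#' Resamples `vol` onto the reference grid through the transform's point
#' map. Label volumes must use `interpolation = "nearest"`, which can only
#' preserve or reduce the label set.
#'
#' @param vol an [image_volume] (the moving image).
#' @param t an [atlas_transform].
#' @param reference an [image_volume] or grid descriptor defining the
#'   output grid; defaults to the transform's reference, else `vol`'s grid.
#' @param interpolation `"linear"`, `"nearest"` or `"bspline"`.
#' @param fill value for points mapping outside `vol`.
#' @return an [image_volume] on the reference grid.
#' @export
apply_transform <- function(vol, t, reference = NULL,
                            interpolation = "linear", fill = 0) {
  stopifnot(is_image_volume(vol), is_transform(t))
  g <- if (is.null(reference)) {
    if (!is.null(t$reference)) t$reference else vol_grid(vol)
  } else if (is_image_volume(reference)) vol_grid(reference) else reference
  disp <- NULL
  if (!is.null(t$warp)) {
    if (grids_equal(t$reference, g)) {
      disp <- as.numeric(t$warp)
    } else {
      disp <- as.numeric(resample_field(t$warp, t$reference, g))
    }
  }
  sg <- vol_grid(vol)
  out <- cpp_warp(as.numeric(vol$data), as.integer(sg$dim), sg$spacing,
                  sg$origin, as.integer(g$dim), g$spacing, g$origin,
                  t$affine, disp, interp_code(interpolation), fill)
  image_volume(array(out, g$dim), spacing = g$spacing, origin = g$origin,
               orientation = vol$orientation)
}

# resample a displacement field (c(dim,3) array on grid `from`) onto `to`
resample_field <- function(warp, from, to) {
  n_from <- prod(from$dim)
  out <- array(0, c(to$dim, 3))
  for (ax in 1:3) {
    comp <- array(warp[seq_len(n_from) + (ax - 1) * n_from], from$dim)
    out[, , , ax] <- array(
      cpp_warp(as.numeric(comp), as.integer(from$dim), from$spacing,
               from$origin, as.integer(to$dim), to$spacing, to$origin,
               diag(4), NULL, 2L, 0), to$dim)
  }
  out
}

#' Compose transforms
#'
#' `compose_transforms(list(t1, t2))` returns the single transform whose
#' application to a volume equals applying `t1` first, then `t2`. In
#' pull-back terms the composite point map is `T1(T2(p))`; for pure
#' affines the composite matrix is `A1 %*% A2` (verified against
#' sequential application on random points).
#'
#' @param ts list of [atlas_transform]s, in application order.
#' @param reference grid for the composite warp when any member is
#'   nonlinear; defaults to the last nonlinear member's reference.
#' @param with_inverse also compute the composite's inverse field.
#' @return an [atlas_transform].
#' @export
compose_transforms <- function(ts, reference = NULL, with_inverse = TRUE) {
  stopifnot(length(ts) >= 1, all(vapply(ts, is_transform, logical(1))))
  if (length(ts) == 1L) return(ts[[1]])
  nonlin <- vapply(ts, function(t) !is.null(t$warp), logical(1))
  if (!any(nonlin)) {
    A <- Reduce(`%*%`, lapply(ts, `[[`, "affine"))
    return(atlas_transform(A, reference = reference))
  }
  if (is.null(reference)) {
    last_nl <- ts[[max(which(nonlin))]]
    reference <- last_nl$reference
  }
  g <- reference
  n <- prod(g$dim)
  # composite total displacement built right-to-left: with utot holding
  # T_rest(p) - p, prepending T gives T(p + utot(p)) - p
  utot <- array(0, c(g$dim, 3))
  first <- TRUE
  for (t in rev(ts)) {
    if (first) {
      utot <- total_displacement_on(t, g)
      first <- FALSE
      next
    }
    uw <- matrix(0, n, 3)
    if (!is.null(t$warp)) {
      wg <- t$reference
      for (ax in 1:3) {
        comp <- array(t$warp[seq_len(prod(wg$dim)) +
                               (ax - 1) * prod(wg$dim)], wg$dim)
        uw[, ax] <- cpp_warp(as.numeric(comp), as.integer(wg$dim),
                             wg$spacing, wg$origin, as.integer(g$dim),
                             g$spacing, g$origin, diag(4),
                             as.numeric(utot), 2L, 0)
      }
    }
    idx <- arrayInd(seq_len(n), g$dim) - 1L
    p <- sweep(sweep(idx, 2, g$spacing, "*"), 2, g$origin, "+")
    q <- p + matrix(utot, n, 3)
    q <- cbind(q, 1) %*% t(t$affine)
    utot <- array(q[, 1:3] + uw - p, c(g$dim, 3))
  }
  inv <- if (with_inverse) invert_field(utot, g) else NULL
  atlas_transform(diag(4), warp = utot, inverse_warp = inv, reference = g)
}

#' Invert a transform
#'
#' Affines are inverted exactly; dense warps by fixed-point iteration on
#' the displacement field (accurate for the smooth, modest-magnitude
#' fields used here).
#'
#' @param t an [atlas_transform].
#' @return the inverse [atlas_transform].
#' @export
invert_transform <- function(t) {
  stopifnot(is_transform(t))
  if (is.null(t$warp)) return(atlas_transform(solve(t$affine),
                                              reference = t$reference))
  g <- t$reference
  u <- total_displacement_on(t, g)
  # inverse_warp, when present, already holds the total inverse displacement
  inv <- if (!is.null(t$inverse_warp)) t$inverse_warp else invert_field(u, g)
  atlas_transform(diag(4), warp = inv, inverse_warp = array(u, c(g$dim, 3)),
                  reference = g)
}

# fixed-point inversion: u_inv(p) = -u(p + u_inv(p)); iterate until the
# update stalls (geometric convergence for fields with |grad u| < 1)
invert_field <- function(u, g, iters = 30L, tol = 1e-3) {
  n <- prod(g$dim)
  uin <- array(0, c(g$dim, 3))
  for (it in seq_len(iters)) {
    samp <- array(0, c(g$dim, 3))
    for (ax in 1:3) {
      comp <- array(u[seq_len(n) + (ax - 1) * n], g$dim)
      samp[, , , ax] <- array(
        cpp_warp(as.numeric(comp), as.integer(g$dim), g$spacing, g$origin,
                 as.integer(g$dim), g$spacing, g$origin, diag(4),
                 as.numeric(uin), 2L, 0), g$dim)
    }
    delta <- max(abs(-samp - uin))
    uin <- -samp
    if (delta < tol * min(g$spacing)) break
  }
  uin
}

#' Average transforms
#'
#' Displacement fields are averaged voxel-wise; affines in the matrix-log
#' domain (the geodesic mean for well-conditioned transforms), so the
#' average of two pure translations is their midpoint and the average of
#' `{+d, -d}` displacement pairs is the zero field.
#'
#' @param ts list of [atlas_transform]s sharing one reference grid.
#' @return an [atlas_transform].
#' @export
average_transforms <- function(ts) {
  stopifnot(length(ts) >= 1, all(vapply(ts, is_transform, logical(1))))
  refs <- lapply(ts, `[[`, "reference")
  ref <- refs[[which(!vapply(refs, is.null, logical(1)))[1]]]
  if (!is.null(ref)) {
    for (r in refs)
      if (!is.null(r) && !grids_equal(r, ref))
        stop("average_transforms: mixed reference grids", call. = FALSE)
  }
  logs <- lapply(ts, function(t) mat_logm(t$affine))
  A <- mat_expm(Reduce(`+`, logs) / length(ts))
  A[4, ] <- c(0, 0, 0, 1)
  warps <- lapply(ts, `[[`, "warp")
  have <- !vapply(warps, is.null, logical(1))
  w <- NULL
  if (any(have)) {
    zero <- array(0, c(ref$dim, 3))
    warps[!have] <- list(zero)
    w <- Reduce(`+`, warps) / length(ts)
  }
  inv <- if (!is.null(w)) invert_field(w, ref) else NULL
  atlas_transform(A, warp = w, inverse_warp = inv, reference = ref)
}

#' Serialize / deserialize a transform
#'
#' The affine is written as a plain-text 4x4 matrix (`<path>.affine.txt`);
#' warp and inverse warp as NIfTI volumes with the three displacement
#' components stacked along a fourth dimension
#' (`<path>.warp.nii.gz`, `<path>.invwarp.nii.gz`); the reference grid in
#' `<path>.grid.json`. Round-trips are bit-exact for the affine and exact
#' to float64 NIfTI storage for the fields.
#'
#' @param t an [atlas_transform].
#' @param path basename (no extension) for the component files.
#' @return `path` invisibly / the reloaded [atlas_transform].
#' @export
save_transform <- function(t, path) {
  stopifnot(is_transform(t))
  write.table(t$affine, paste0(path, ".affine.txt"), row.names = FALSE,
              col.names = FALSE)
  if (!is.null(t$reference))
    jsonlite::write_json(t$reference, paste0(path, ".grid.json"),
                         digits = NA)
  wrt <- function(w, suffix) {
    img <- RNifti::asNifti(array(w, c(dim(w)[1:3], 1, 3)))
    RNifti::pixdim(img) <- t$reference$spacing
    RNifti::writeNifti(img, paste0(path, suffix))
  }
  if (!is.null(t$warp)) wrt(t$warp, ".warp.nii.gz")
  if (!is.null(t$inverse_warp)) wrt(t$inverse_warp, ".invwarp.nii.gz")
  invisible(path)
}

#' @rdname save_transform
#' @export
load_transform <- function(path) {
  A <- as.matrix(read.table(paste0(path, ".affine.txt")))
  dimnames(A) <- NULL
  ref <- NULL
  gp <- paste0(path, ".grid.json")
  if (file.exists(gp)) {
    ref <- jsonlite::fromJSON(gp)
    ref$dim <- as.integer(ref$dim)
  }
  rd <- function(suffix) {
    f <- paste0(path, suffix)
    if (!file.exists(f)) return(NULL)
    w <- as.array(RNifti::readNifti(f))
    array(w, c(dim(w)[1:3], 3))
  }
  atlas_transform(A, warp = rd(".warp.nii.gz"),
                  inverse_warp = rd(".invwarp.nii.gz"), reference = ref)
}
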