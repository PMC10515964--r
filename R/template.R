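#' Cohort of subjects for template construction
#'
#' A cohort is an ordered list of subject records, each holding a primary
#' channel (the contrast driving registration) and optionally co-registered
#' sibling contrasts on the same subject grid (e.g. T2w, FA, DWI, ADC).
#'
#' @param records list of [subject_record()]s.
#' @return a `cohort` object.
#' @export
cohort <- function(records = list()) {
  stopifnot(all(vapply(records, inherits, logical(1), "subject_record")))
  structure(list(records = records), class = "cohort")
}

#' @rdname cohort
#' @param id subject identifier.
#' @param primary primary-channel [image_volume].
#' @param contrasts named list of sibling-contrast [image_volume]s.
#' @param reflected whether this record is a midline reflection.
#' @export
subject_record <- function(id, primary, contrasts = list(),
                           reflected = FALSE) {
  stopifnot(is_image_volume(primary))
  structure(list(id = id, primary = primary, contrasts = contrasts,
                 reflected = reflected),
            class = "subject_record")
}

#' @export
length.cohort <- function(x) length(x$records)

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%d reflected)\n", length(x),
              sum(vapply(x$records, `[[`, logical(1), "reflected"))))
  invisible(x)
}

#' Reflect a volume across the midsagittal plane
#'
#' Flips the left-right axis (the first axis under the RAS convention):
#' voxel (i, j, k) maps to (N-1-i, j, k). The world grid is unchanged, so
#' the midline is the grid's x-center plane and reflecting twice is the
#' identity.
#'
#' @param vol an [image_volume]; its orientation code must name the
#'   left-right axis first (R or L).
#' @return the reflected [image_volume].
#' @export
reflect_midsagittal <- function(vol) {
  stopifnot(is_image_volume(vol))
  ax <- substr(vol$orientation, 1, 1)
  if (!ax %in% c("R", "L"))
    stop("reflect_midsagittal: orientation '", vol$orientation,
         "' does not put the left-right axis first", call. = FALSE)
  d <- dim(vol$data)
  image_volume(vol$data[d[1]:1, , , drop = FALSE], vol$spacing, vol$origin,
               vol$orientation)
}

#' Double a cohort with midline reflections
#'
#' Appends, for every subject, a copy with all channels reflected across
#' the midsagittal plane and flagged `reflected`. Feeding the doubled
#' cohort to [build_template()] makes the resulting template mirror
#' symmetric by construction.
#'
#' @param c a [cohort()].
#' @return a [cohort()] of twice the size.
#' @export
symmetrize_cohort <- function(c) {
  stopifnot(inherits(c, "cohort"))
  refl <- lapply(c$records, function(r)
    subject_record(paste0(r$id, "_refl"),
                   reflect_midsagittal(r$primary),
                   lapply(r$contrasts, reflect_midsagittal),
                   reflected = TRUE))
  cohort(c(c$records, refl))
}

#' Build a morphology- and intensity-averaged template
#'
#' Starting from the voxel-wise mean of the input cohort, each iteration
#' (1) registers every input to the current template, (2) voxel-wise
#' averages the warped inputs, and (3) applies the inverse of the average
#' transform to that average, which removes the cohort-mean shape bias
#' from the template. Intensities are rescaled per subject only inside the
#' registration metric; template intensities are averaged on the native
#' scale so sibling-contrast propagation stays linear.
#'
#' @param c a [cohort()]; all primary channels must share one grid.
#' @param spec a [registration_spec()]; the default uses nonlinear demons
#'   only, appropriate once subjects share a grid.
#' @param n_iter number of iterations (>= 1).
#' @param early_stop stop when the mean update displacement falls below
#'   this fraction of a voxel (0 disables).
#' @return a `template_result`: `template` ([image_volume], primary
#'   contrast), `transforms` (per subject), `convergence` (data frame of
#'   per-iteration mean update displacement and intensity change) and
#'   `contrast_templates` (filled by [propagate_contrasts()]).
#' @export
build_template <- function(c, spec = registration_spec(mode = "nonlinear"),
                           n_iter = 4L, early_stop = 0.1) {
  stopifnot(inherits(c, "cohort"), n_iter >= 1L)
  n <- length(c)
  if (n == 0L) stop("build_template: empty cohort", call. = FALSE)
  g <- vol_grid(c$records[[1]]$primary)
  for (r in c$records)
    if (!grids_equal(vol_grid(r$primary), g))
      stop("build_template: primary channels on different grids (subject ",
           r$id, ")", call. = FALSE)
  datas <- lapply(c$records, function(r) r$primary$data)
  template <- image_volume(Reduce(`+`, datas) / n, g$spacing, g$origin,
                           c$records[[1]]$primary$orientation)
  transforms <- NULL
  conv <- data.frame(iteration = integer(0), mean_update_vox = numeric(0),
                     intensity_change = numeric(0))
  for (it in seq_len(n_iter)) {
    transforms <- vector("list", n)
    warped <- vector("list", n)
    for (i in seq_len(n)) {
      t_i <- tryCatch(
        register(template, c$records[[i]]$primary, spec),
        error = function(e)
          stop("build_template: registration failed for subject ",
               c$records[[i]]$id, ": ", conditionMessage(e), call. = FALSE))
      transforms[[i]] <- t_i
      warped[[i]] <- apply_transform(c$records[[i]]$primary, t_i,
                                     reference = g)
    }
    avg_img <- image_volume(Reduce(`+`, lapply(warped, `[[`, "data")) / n,
                            g$spacing, g$origin, template$orientation)
    avg_t <- average_transforms(transforms)
    upd <- invert_transform(avg_t)
    new_template <- apply_transform(avg_img, upd, reference = g)
    mean_upd <- mean(sqrt(rowSums(matrix(
      total_displacement_on(avg_t, g), prod(g$dim), 3)^2))) /
      mean(g$spacing)
    dI <- mean(abs(new_template$data - template$data))
    conv <- rbind(conv, data.frame(iteration = it,
                                   mean_update_vox = mean_upd,
                                   intensity_change = dI))
    template <- new_template
    # the template was just shape-updated; compose each subject transform
    # with the update so the returned transforms map into the returned
    # template's space (this also centers their voxel-wise mean)
    transforms <- lapply(transforms, function(t)
      compose_transforms(list(t, upd), reference = g,
                         with_inverse = FALSE))
    if (early_stop > 0 && mean_upd < early_stop && it < n_iter) break
  }
  # final intensity average under the final (composed) transforms, so the
  # returned template is exactly the mean of the warped subjects — the
  # identity sibling-contrast propagation then reproduces it bit for bit
  template <- image_volume(
    Reduce(`+`, lapply(seq_len(n), function(i)
      apply_transform(c$records[[i]]$primary, transforms[[i]],
                      reference = g)$data)) / n,
    g$spacing, g$origin, template$orientation)
  structure(list(template = template, transforms = transforms,
                 convergence = conv, cohort_ids =
                   vapply(c$records, `[[`, character(1), "id"),
                 grid = g, contrast_templates = list()),
            class = "template_result")
}

#' @export
print.template_result <- function(x, ...) {
  cat(sprintf("<template_result> %s grid, %d subjects, %d iterations\n",
              paste(x$grid$dim, collapse = "x"), length(x$transforms),
              nrow(x$convergence)))
  print(x$convergence, row.names = FALSE)
  invisible(x)
}

#' Propagate template construction to sibling contrasts
#'
#' Applies each subject's final subject-to-template transform, unchanged,
#' to every sibling contrast and averages the warped volumes per contrast.
#' Transforms are never re-estimated, so a contrast that is a linear
#' function of the primary yields exactly that function of the primary
#' template.
#'
#' @param result a `template_result` from [build_template()].
#' @param c the same [cohort()] the template was built from.
#' @param missing_policy `"skip"` averages over the subjects that have the
#'   contrast; `"error"` aborts when any subject lacks it.
#' @return `result` with `contrast_templates` filled (named list of
#'   [image_volume]s) and `contrast_counts` recording how many subjects
#'   entered each average.
#' @export
propagate_contrasts <- function(result, c,
                                missing_policy = c("skip", "error")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(result, "template_result"), inherits(c, "cohort"))
  g <- result$grid
  names_all <- unique(unlist(lapply(c$records, function(r)
    names(r$contrasts))))
  out <- list(); counts <- integer(0)
  for (cn in names_all) {
    acc <- NULL; k <- 0L
    for (i in seq_along(c$records)) {
      v <- c$records[[i]]$contrasts[[cn]]
      if (is.null(v)) {
        if (missing_policy == "error")
          stop("propagate_contrasts: contrast ", cn, " missing for subject ",
               c$records[[i]]$id, call. = FALSE)
        next
      }
      w <- apply_transform(v, result$transforms[[i]], reference = g)
      acc <- if (is.null(acc)) w$data else acc + w$data
      k <- k + 1L
    }
    if (k > 0L) {
      out[[cn]] <- image_volume(acc / k, g$spacing, g$origin)
      counts[cn] <- k
    }
  }
  result$contrast_templates <- out
  result$contrast_counts <- counts
  result
}

#' Staged coarse-to-fine template construction
#'
#' Runs [build_template()] at a sequence of strictly decreasing spacings,
#' each stage initializing registration targets from the upsampled
#' previous template (the staging used to keep large-volume template
#' construction tractable: coarse first, then refine).
#'
#' @param c a [cohort()] at the finest resolution.
#' @param resolutions ordered vector of isotropic spacings (mm),
#'   coarse to fine; the last stage runs at the cohort's native grid if
#'   its spacing matches, otherwise volumes are resampled.
#' @param spec a [registration_spec()].
#' @param n_iter iterations per stage (recycled).
#' @return the final stage's `template_result`, with `stages` recording
#'   each stage's convergence.
#' @export
staged_multires_build <- function(c, resolutions,
                                  spec = registration_spec(mode = "nonlinear"),
                                  n_iter = 4L) {
  stopifnot(inherits(c, "cohort"), length(resolutions) >= 1)
  if (any(diff(resolutions) >= 0))
    stop("staged_multires_build: resolutions must strictly decrease",
         call. = FALSE)
  n_iter <- rep_len(n_iter, length(resolutions))
  stages <- list()
  init_template <- NULL
  result <- NULL
  for (si in seq_along(resolutions)) {
    sp <- resolutions[si]
    cr <- cohort(lapply(c$records, function(r)
      subject_record(r$id, resample_volume(r$primary, sp), r$contrasts,
                     r$reflected)))
    if (!is.null(init_template)) {
      # initialize this stage's first registration target from the
      # upsampled previous template rather than the cohort mean
      tpl0 <- resample_volume(init_template, sp)
      result <- build_template_from(cr, tpl0, spec, n_iter[si])
    } else {
      result <- build_template(cr, spec, n_iter[si])
    }
    stages[[si]] <- result$convergence
    init_template <- result$template
  }
  result$stages <- stages
  result
}

# build_template with an explicit initial template estimate
build_template_from <- function(c, template0, spec, n_iter) {
  g <- vol_grid(c$records[[1]]$primary)
  tpl0 <- if (grids_equal(vol_grid(template0), g)) template0 else
    apply_transform(template0, identity_transform(), reference = g)
  n <- length(c)
  template <- tpl0
  transforms <- NULL
  conv <- data.frame(iteration = integer(0), mean_update_vox = numeric(0),
                     intensity_change = numeric(0))
  for (it in seq_len(n_iter)) {
    transforms <- vector("list", n)
    warped <- vector("list", n)
    for (i in seq_len(n)) {
      t_i <- register(template, c$records[[i]]$primary, spec)
      transforms[[i]] <- t_i
      warped[[i]] <- apply_transform(c$records[[i]]$primary, t_i,
                                     reference = g)
    }
    avg_img <- image_volume(Reduce(`+`, lapply(warped, `[[`, "data")) / n,
                            g$spacing, g$origin)
    avg_t <- average_transforms(transforms)
    upd <- invert_transform(avg_t)
    new_template <- apply_transform(avg_img, upd, reference = g)
    mean_upd <- mean(sqrt(rowSums(matrix(
      total_displacement_on(avg_t, g), prod(g$dim), 3)^2))) /
      mean(g$spacing)
    conv <- rbind(conv, data.frame(iteration = it,
                                   mean_update_vox = mean_upd,
                                   intensity_change =
                                     mean(abs(new_template$data -
                                                template$data))))
    template <- new_template
    transforms <- lapply(transforms, function(t)
      compose_transforms(list(t, upd), reference = g,
                         with_inverse = FALSE))
  }
  template <- image_volume(
    Reduce(`+`, lapply(seq_len(n), function(i)
      apply_transform(c$records[[i]]$primary, transforms[[i]],
                      reference = g)$data)) / n,
    g$spacing, g$origin)
  structure(list(template = template, transforms = transforms,
                 convergence = conv,
                 cohort_ids = vapply(c$records, `[[`, character(1), "id"),
                 grid = g, contrast_templates = list()),
            class = "template_result")
}

#' Relative mirror asymmetry of a volume
#'
#' `||v - reflect(v)||_1 / ||v||_1`; 0 for an exactly mirror-symmetric
#' volume.
#'
#' @param vol an [image_volume].
#' @export
mirror_asymmetry <- function(vol) {
  r <- reflect_midsagittal(vol)
  s <- sum(abs(vol$data))
  if (s == 0) return(0)
  sum(abs(vol$data - r$data)) / s
}
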