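#' Downsample a binary classification volume into counts
#'
#' Each output voxel holds the number of positive high-resolution voxels
#' in its block, so the total positive count is conserved exactly — the
#' form in which classified-voxel data are carried to annotation
#' resolution.
#'
#' @param binary [image_volume] with values in \{0, 1\}.
#' @param factor per-axis integer downsampling factors (scalar recycled).
#' @return a count [image_volume]; attribute `voxels_per_bin` records the
#'   block capacity.
#' @export
downsample_count <- function(binary, factor) {
  stopifnot(is_image_volume(binary))
  if (!all(binary$data %in% c(0, 1)))
    stop("downsample_count: input must be binary", call. = FALSE)
  f <- as.integer(rep_len(factor, 3))
  if (any(f < 1)) stop("downsample_count: factor must be >= 1",
                       call. = FALSE)
  g <- vol_grid(binary)
  out <- cpp_block_sum(as.numeric(binary$data), as.integer(g$dim), f)
  v <- image_volume(array(out, dim(out)), spacing = g$spacing * f,
                    origin = g$origin + (f - 1) * g$spacing / 2,
                    orientation = binary$orientation)
  attr(v, "voxels_per_bin") <- prod(f)
  v
}

#' Relative occupancy per anatomical region
#'
#' For every region present in the annotation: the sum of positive-voxel
#' counts, the region's voxel count at annotation resolution, and their
#' ratio. The denominator is `region_voxels * voxels_per_bin`, so a ratio
#' of 1 means fully occupied at classification resolution. With
#' `rollup = TRUE`, every ancestor region also gets a row summing its
#' descendants (aggregating child rows to a parent reproduces the parent
#' row exactly).
#'
#' @param counts count [image_volume] (e.g. from [downsample_count()],
#'   warped to the annotation grid).
#' @param annot an [annotation_volume()] on the same grid.
#' @param voxels_per_bin positive-voxel capacity of one annotation voxel;
#'   default from the `counts` attribute, else 1.
#' @param rollup add ancestor rows aggregated over descendants.
#' @return an `occupancy_table` data frame: region_id, acronym, positive,
#'   region_voxels, ratio.
#' @export
regional_occupancy <- function(counts, annot, voxels_per_bin = NULL,
                               rollup = FALSE) {
  stopifnot(inherits(annot, "annotation_volume"))
  if (!same_grid(counts, annot$labels))
    stop("regional_occupancy: grid mismatch", call. = FALSE)
  if (is.null(voxels_per_bin))
    voxels_per_bin <- attr(counts, "voxels_per_bin")
  if (is.null(voxels_per_bin)) voxels_per_bin <- 1
  lab <- as.integer(annot$labels$data)
  cnt <- as.numeric(counts$data)
  keep <- lab != 0L
  pos <- rowsum(cnt[keep], lab[keep])
  vox <- rowsum(rep(1L, sum(keep)), lab[keep])
  ids <- as.integer(rownames(pos))
  df <- data.frame(region_id = ids,
                   positive = as.numeric(pos),
                   region_voxels = as.integer(vox))
  if (rollup) {
    ont <- annot$ontology
    extra <- list()
    for (anc in ont$table$id16) {
      desc <- descendants_of(ont, anc)
      rows <- df$region_id %in% c(anc, desc)
      if (!any(rows) || (sum(rows) == 1 && df$region_id[rows][1] == anc))
        next
      extra[[length(extra) + 1L]] <- data.frame(
        region_id = anc, positive = sum(df$positive[rows]),
        region_voxels = sum(df$region_voxels[rows]))
    }
    base_ids <- df$region_id
    if (length(extra) > 0) {
      extra <- do.call(rbind, extra)
      extra <- extra[!(extra$region_id %in% base_ids), , drop = FALSE]
      df <- rbind(df, extra)
    }
  }
  acr <- annot$ontology$table$acronym[match(df$region_id,
                                            annot$ontology$table$id16)]
  df$acronym <- acr
  df$ratio <- df$positive / (df$region_voxels * voxels_per_bin)
  df <- df[order(df$region_id), c("region_id", "acronym", "positive",
                                  "region_voxels", "ratio")]
  rownames(df) <- NULL
  attr(df, "voxels_per_bin") <- voxels_per_bin
  class(df) <- c("occupancy_table", "data.frame")
  df
}

descendants_of <- function(ont, id) {
  out <- integer(0)
  frontier <- id
  repeat {
    kids <- ont$table$id16[!is.na(ont$table$parent_id16) &
                             ont$table$parent_id16 %in% frontier]
    if (length(kids) == 0) break
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Cell-type by region proportion matrix
#'
#' Assigns each cell to the annotation voxel containing its coordinates
#' (flooring world-to-index, a deterministic boundary rule) and tabulates,
#' per subclass, the proportion of its cells falling in each region.
#' Cells outside the annotation extent count toward an `unassigned` row,
#' so every subclass column sums to exactly 1.
#'
#' @param cells data frame with columns `x_mm`, `y_mm`, `z_mm`,
#'   `subclass` (and optionally `class`).
#' @param annot an [annotation_volume()].
#' @return numeric matrix (regions + "unassigned") x subclasses of
#'   proportions; integer counts in attribute `counts`.
#' @export
cell_type_distribution <- function(cells, annot) {
  if (nrow(cells) == 0)
    stop("cell_type_distribution: empty cell table", call. = FALSE)
  req <- c("x_mm", "y_mm", "z_mm", "subclass")
  stopifnot(all(req %in% names(cells)))
  if (any(!is.finite(as.matrix(cells[, c("x_mm", "y_mm", "z_mm")]))))
    stop("cell_type_distribution: non-finite coordinates", call. = FALSE)
  g <- vol_grid(annot$labels)
  idx <- floor(sweep(sweep(as.matrix(cells[, c("x_mm", "y_mm", "z_mm")]),
                           2, g$origin), 2, g$spacing, "/") + 0.5)
  inside <- idx[, 1] >= 0 & idx[, 2] >= 0 & idx[, 3] >= 0 &
    idx[, 1] < g$dim[1] & idx[, 2] < g$dim[2] & idx[, 3] < g$dim[3]
  lab <- rep(NA_integer_, nrow(cells))
  lin <- 1 + idx[inside, 1] + g$dim[1] * (idx[inside, 2] +
                                            g$dim[2] * idx[inside, 3])
  lab[inside] <- as.integer(annot$labels$data)[lin]
  region <- ifelse(is.na(lab) | lab == 0L, "unassigned",
                   as.character(lab))
  tab <- table(region, as.character(cells$subclass))
  cnt <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                dimnames = dimnames(tab))
  prop <- sweep(cnt, 2, colSums(cnt), "/")
  attr(prop, "counts") <- cnt
  prop
}

#' Magnetization transfer ratio map
#'
#' Voxel-wise `MTR = 1 - MT/M0`; voxels with nonpositive M0 are set to
#' `NA` (masked sentinel).
#'
#' @param mt,m0 [image_volume]s on one grid.
#' @return the MTR [image_volume].
#' @export
compute_mtr <- function(mt, m0) {
  if (!same_grid(mt, m0)) stop("compute_mtr: grid mismatch", call. = FALSE)
  out <- 1 - mt$data / m0$data
  out[m0$data <= 0] <- NA_real_
  image_volume(out, mt$spacing, mt$origin, mt$orientation)
}

#' Mass-preserving warp of a count volume
#'
#' Linear-interpolation warping scaled by the local volume change
#' (Jacobian determinant of the map), keeping the total count conserved
#' to within interpolation error; `jacobian = FALSE` reproduces the naive
#' resampling behavior.
#'
#' @param counts count [image_volume].
#' @param t an [atlas_transform].
#' @param reference output grid.
#' @param jacobian apply the Jacobian-determinant scaling.
#' @return the warped count [image_volume].
#' @export
warp_counts <- function(counts, t, reference = NULL, jacobian = TRUE) {
  out <- apply_transform(counts, t, reference = reference,
                         interpolation = "linear")
  if (!jacobian) return(out)
  g <- vol_grid(out)
  u <- total_displacement_on(t, g)
  n <- prod(g$dim)
  # d(T)/dp = I + du/dp: determinant from component gradients
  J <- array(0, c(n, 3, 3))
  for (ax in 1:3)
    J[, ax, ] <- matrix(cpp_gradient3d(as.numeric(u[, , , ax]),
                                       as.integer(g$dim), g$spacing), n, 3)
  detJ <- (1 + J[, 1, 1]) * ((1 + J[, 2, 2]) * (1 + J[, 3, 3]) -
                               J[, 2, 3] * J[, 3, 2]) -
    J[, 1, 2] * (J[, 2, 1] * (1 + J[, 3, 3]) - J[, 2, 3] * J[, 3, 1]) +
    J[, 1, 3] * (J[, 2, 1] * J[, 3, 2] - (1 + J[, 2, 2]) * J[, 3, 1])
  image_volume(array(out$data * array(detJ, g$dim), g$dim), g$spacing,
               g$origin, out$orientation)
}
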