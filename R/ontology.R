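#' Hierarchical developmental ontology
#'
#' A region tree held as a validated table: 16-bit region id, optional
#' original 32-bit id, name, acronym, parent id, color and depth level
#' (root level 0, `level(child) = level(parent) + 1`). Construction
#' validates uniqueness, parent existence, acyclicity and level
#' consistency.
#'
#' @param table data frame with columns `id16`, `name`, `acronym`,
#'   `parent_id16` (NA for the root) and optionally `id32`, `color_hex`,
#'   `level` (recomputed if absent).
#' @return an `ontology` object.
#' @export
ontology <- function(table) {
  req <- c("id16", "name", "acronym", "parent_id16")
  if (!all(req %in% names(table)))
    stop("ontology: missing columns: ",
         paste(setdiff(req, names(table)), collapse = ", "), call. = FALSE)
  table$id16 <- as.integer(table$id16)
  if (any(duplicated(table$id16)))
    stop("ontology: duplicate id16: ",
         paste(unique(table$id16[duplicated(table$id16)]), collapse = ", "),
         call. = FALSE)
  if (any(table$id16 < 0 | table$id16 > 65535))
    stop("ontology: id16 out of 16-bit range", call. = FALSE)
  roots <- which(is.na(table$parent_id16))
  if (length(roots) == 0) stop("ontology: no root region", call. = FALSE)
  known <- table$id16
  orphan <- !is.na(table$parent_id16) & !(table$parent_id16 %in% known)
  if (any(orphan))
    stop("ontology: orphan parent reference in rows: ",
         paste(table$id16[orphan], collapse = ", "), call. = FALSE)
  if (any(!is.na(table$parent_id16) & table$parent_id16 == table$id16))
    stop("ontology: cycle (self-parent) at id ",
         paste(table$id16[!is.na(table$parent_id16) &
                            table$parent_id16 == table$id16],
               collapse = ", "), call. = FALSE)
  # levels by breadth-first walk; leftovers indicate a cycle
  lvl <- rep(NA_integer_, nrow(table))
  lvl[roots] <- 0L
  frontier <- table$id16[roots]
  depth <- 0L
  while (length(frontier) > 0) {
    depth <- depth + 1L
    nxt <- which(table$parent_id16 %in% frontier & is.na(lvl))
    lvl[nxt] <- depth
    frontier <- table$id16[nxt]
  }
  if (any(is.na(lvl)))
    stop("ontology: cycle in parent links involving ids ",
         paste(table$id16[is.na(lvl)], collapse = ", "), call. = FALSE)
  table$level <- lvl
  if (is.null(table$color_hex)) table$color_hex <- NA_character_
  if (is.null(table$id32)) table$id32 <- NA_integer_
  rownames(table) <- NULL
  structure(list(table = table,
                 parent = stats::setNames(table$parent_id16, table$id16),
                 level = stats::setNames(table$level, table$id16)),
            class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %d regions, depth %d\n", nrow(x$table),
              max(x$table$level)))
  invisible(x)
}

#' Load an ontology table from CSV or JSON
#'
#' Columns: `id16`, `id32` (optional), `name`, `acronym`, `parent_id16`
#' (empty/NA for the root), `color_hex`, `level` (recomputed).
#'
#' @param path file path (.csv or .json).
#' @return an [ontology()].
#' @export
load_ontology <- function(path) {
  ext <- tolower(tools::file_ext(path))
  tab <- if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  ontology(tab)
}

#' Remap 32-bit region ids into the 16-bit scheme
#'
#' Ids already within 0-65535 pass through unchanged. Larger ids are
#' folded into the 20000-29999 range by taking the last four decimal
#' digits and prefixing a 2 (arithmetically: `20000 + id %% 10000`),
#' preserving leading zeros. When a vector is remapped as one id set, any
#' collision (two distinct inputs landing on one output) raises an error
#' listing the colliding pairs rather than renumbering silently.
#'
#' @param id32 nonnegative integer id(s).
#' @return integer id16 vector, with a `mapping` attribute
#'   (data frame id32 -> id16) when any id was remapped.
#' @export
remap_id32_to_16 <- function(id32) {
  id32 <- as.numeric(id32)
  if (any(id32 < 0)) stop("remap_id32_to_16: negative id", call. = FALSE)
  out <- ifelse(id32 <= 65535, id32, 20000 + id32 %% 10000)
  dup <- duplicated(out) & !duplicated(id32)
  if (any(dup)) {
    clash <- out[dup][1]
    pair <- id32[out == clash]
    stop("remap_id32_to_16: collision: ids ",
         paste(utils::head(unique(pair), 4), collapse = ", "),
         " all map to ", clash, call. = FALSE)
  }
  res <- as.integer(out)
  if (any(id32 > 65535))
    attr(res, "mapping") <- data.frame(id32 = id32[id32 > 65535],
                                       id16 = res[id32 > 65535])
  res
}

#' Integer annotation volume bound to an ontology
#'
#' Every nonzero voxel label must exist in the ontology; background is 0.
#'
#' @param labels integer [image_volume].
#' @param ont an [ontology()].
#' @return an `annotation_volume`.
#' @export
annotation_volume <- function(labels, ont) {
  stopifnot(is_image_volume(labels), inherits(ont, "ontology"))
  labs <- unique(as.integer(labels$data))
  labs <- labs[labs != 0L]
  unknown <- setdiff(labs, ont$table$id16)
  if (length(unknown) > 0)
    stop("annotation_volume: labels absent from ontology: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  structure(list(labels = labels, ontology = ont),
            class = "annotation_volume")
}

#' @export
print.annotation_volume <- function(x, ...) {
  labs <- unique(as.integer(x$labels$data))
  cat(sprintf("<annotation_volume> %s, %d distinct labels\n",
              paste(dim(x$labels$data), collapse = "x"),
              sum(labs != 0)))
  invisible(x)
}

#' Validate an annotation volume against a brain mask
#'
#' Checks the mutual-exclusivity/exhaustiveness contract: every brain-mask
#' voxel carries exactly one nonzero ontology label. Reports (a) in-mask
#' voxels labeled 0, (b) labels absent from the ontology, (c) labeled
#' voxels outside the mask.
#'
#' @param annot an [annotation_volume()] or integer [image_volume].
#' @param brain_mask binary [image_volume] on the same grid.
#' @param ont ontology (taken from `annot` when it is an
#'   [annotation_volume()]).
#' @return a `validation_report`: pass flag and the three finding lists
#'   (voxel indices / label values).
#' @export
validate_annotation <- function(annot, brain_mask, ont = NULL) {
  if (inherits(annot, "annotation_volume")) {
    if (is.null(ont)) ont <- annot$ontology
    vol <- annot$labels
  } else vol <- annot
  if (!same_grid(vol, brain_mask))
    stop("validate_annotation: grid mismatch", call. = FALSE)
  lab <- as.integer(vol$data)
  m <- brain_mask$data > 0
  unlabeled <- which(m & lab == 0L)
  labs <- unique(lab[lab != 0L])
  unknown <- if (is.null(ont)) integer(0) else
    setdiff(labs, ont$table$id16)
  outside <- which(!m & lab != 0L)
  structure(list(pass = length(unlabeled) == 0 && length(unknown) == 0 &&
                   length(outside) == 0,
                 unlabeled_in_mask = unlabeled,
                 unknown_labels = unknown,
                 labeled_outside_mask = outside),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s: %d unlabeled in mask, %d unknown labels, %d labeled outside mask\n",
              if (x$pass) "PASS" else "FAIL",
              length(x$unlabeled_in_mask), length(x$unknown_labels),
              length(x$labeled_outside_mask)))
  invisible(x)
}

# ancestor of each id at a target level (or the id itself when at/above)
ancestor_at_level <- function(ont, ids, level) {
  vapply(ids, function(id) {
    if (id == 0L) return(0L)
    cur <- id
    while (!is.na(cur) && ont$level[as.character(cur)] > level) {
      p <- ont$parent[as.character(cur)]
      if (is.na(p)) break
      cur <- p
    }
    as.integer(cur)
  }, integer(1))
}

#' Aggregate an annotation volume to an ontology level
#'
#' Replaces each voxel's label by its ancestor at the target depth;
#' labels already at or above that depth are kept (with a warning when a
#' root is shallower than requested ancestors cannot exist). Total
#' labeled voxel count is conserved.
#'
#' @param annot an [annotation_volume()].
#' @param level target depth (root = 0).
#' @return an [annotation_volume()] at the coarser level.
#' @export
aggregate_to_level <- function(annot, level) {
  stopifnot(inherits(annot, "annotation_volume"), level >= 0)
  ont <- annot$ontology
  lab <- as.integer(annot$labels$data)
  uniq <- unique(lab)
  map <- ancestor_at_level(ont, uniq, level)
  shallow <- uniq != 0L & ont$level[as.character(uniq)] < level
  shallow[is.na(shallow)] <- FALSE
  if (any(shallow))
    warning("aggregate_to_level: ", sum(shallow),
            " label(s) shallower than level ", level, " kept as-is",
            call. = FALSE)
  lut <- stats::setNames(map, uniq)
  newlab <- lut[as.character(lab)]
  vol <- image_volume(array(as.integer(newlab), dim(annot$labels$data)),
                      annot$labels$spacing, annot$labels$origin,
                      annot$labels$orientation)
  annotation_volume(vol, ont)
}

#' Voxel-wise label contingency table between two annotations
#'
#' Cell (a, b) counts voxels labeled `a` in A and `b` in B; row sums are
#' A's region volumes and column sums B's (exact integer identities).
#' `as_long = TRUE` returns the long-format table (label_a, label_b,
#' voxels) used for Sankey-style exports; the figure-side log scaling is
#' left to the renderer.
#'
#' @param annotA,annotB [annotation_volume()]s (or integer
#'   [image_volume]s) on one grid (warp B beforehand if needed).
#' @param as_long return a long data frame instead of a matrix.
#' @return integer matrix with dimnames of the label values, or a data
#'   frame.
#' @export
crosstab_labels <- function(annotA, annotB, as_long = FALSE) {
  va <- if (inherits(annotA, "annotation_volume")) annotA$labels else annotA
  vb <- if (inherits(annotB, "annotation_volume")) annotB$labels else annotB
  if (!same_grid(va, vb))
    stop("crosstab_labels: grid mismatch", call. = FALSE)
  tab <- table(factor(as.integer(va$data)), factor(as.integer(vb$data)))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  if (!as_long) return(m)
  df <- as.data.frame(as.table(tab), stringsAsFactors = FALSE)
  names(df) <- c("label_a", "label_b", "voxels")
  df$voxels <- as.integer(df$voxels)
  df[df$voxels > 0, ]
}

#' Allocate ids for newly added structures
#'
#' New structures receive ids from 18000 upward; the allocator refuses to
#' exceed 19999 (20000+ is reserved for remapped 32-bit ids).
#'
#' @param ont an [ontology()].
#' @param n number of ids to allocate.
#' @return integer vector of fresh ids.
#' @export
allocate_new_ids <- function(ont, n = 1L) {
  used <- ont$table$id16
  pool <- setdiff(18000:19999, used)
  if (length(pool) < n)
    stop("allocate_new_ids: new-structure id range 18000-19999 exhausted",
         call. = FALSE)
  pool[seq_len(n)]
}
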