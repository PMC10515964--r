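#' Tile and tile-grid containers for light-sheet stitching
#'
#' A tile wraps its voxel data behind a chunked, instrumented reader: data
#' are only accessible in z-blocks of `block_size` slices and every chunk
#' access is counted, which lets tests assert the stitching pipeline's
#' two-read guarantee (edge collection reads each chunk once, fusion reads
#' it once more, and nothing else touches raw data).
#'
#' @param data rank-3 array (x, y, z).
#' @param col,row 1-based grid position.
#' @param overlap nominal overlap fraction in (0, 0.5].
#' @param block_size chunk depth in slices.
#' @return a `tile` object.
#' @export
new_tile <- function(data, col, row, overlap, block_size = 32L) {
  stopifnot(length(dim(data)) == 3L)
  if (overlap <= 0 || overlap > 0.5)
    stop("new_tile: overlap fraction must be in (0, 0.5]", call. = FALSE)
  env <- new.env(parent = emptyenv())
  env$data <- data
  nb <- ceiling(dim(data)[3] / block_size)
  env$reads <- integer(nb)
  structure(list(env = env, col = col, row = row, overlap = overlap,
                 block_size = as.integer(block_size), dim = dim(data),
                 n_blocks = as.integer(nb)),
            class = "tile")
}

# chunked, counted access to raw tile data
read_chunk <- function(tile, b) {
  z0 <- (b - 1L) * tile$block_size + 1L
  z1 <- min(b * tile$block_size, tile$dim[3])
  tile$env$reads[b] <- tile$env$reads[b] + 1L
  tile$env$data[, , z0:z1, drop = FALSE]
}

#' Raw-data chunk read counters
#'
#' Per-chunk read counts of a tile (or a matrix of them for a grid) —
#' the instrumentation behind the pipeline's two-read guarantee.
#'
#' @param x a `tile` or `tile_grid`.
#' @param ... unused.
#' @return integer vector (tile) or tiles x chunks matrix (grid).
#' @export
chunk_reads <- function(x, ...) UseMethod("chunk_reads")

#' @rdname chunk_reads
#' @export
chunk_reads.tile <- function(x, ...) x$env$reads

#' @rdname chunk_reads
#' @export
chunk_reads.tile_grid <- function(x, ...)
  do.call(rbind, lapply(x$tiles, chunk_reads))

#' @rdname new_tile
#' @param tiles named list of tiles (`c{col}_r{row}`).
#' @param cols,rows grid size.
#' @param spacing voxel spacing (mm).
#' @export
tile_grid <- function(tiles, cols, rows, overlap, spacing = c(1, 1, 1),
                      block_size = 32L) {
  d <- tiles[[1]]$dim
  zc <- vapply(tiles, function(t) t$dim[3], numeric(1))
  if (diff(range(zc)) > 0.05 * d[3])
    stop("tile_grid: tiles disagree on slice count", call. = FALSE)
  structure(list(tiles = tiles, cols = cols, rows = rows, overlap = overlap,
                 tile_dim = d, spacing = spacing,
                 stride = c(round(d[1] * (1 - overlap)),
                            round(d[2] * (1 - overlap))),
                 block_size = as.integer(block_size)),
            class = "tile_grid")
}

#' Collect edge strips and their block MIPs (stitching pass 1)
#'
#' Reads the raw tile once, chunk by chunk, keeping only the four outer
#' edge strips (a fraction `edge_fraction` of the tile width/height) and
#' computing, per strip, a maximum-intensity projection along z for every
#' block of `block_size` slices. The retained strips are what all later
#' alignment works on; raw data are not touched again until fusion.
#'
#' @param tile a [new_tile()].
#' @param edge_fraction strip width as a fraction of tile extent, (0, 0.5].
#' @param block_size z-block depth for the MIPs (slices).
#' @return an `edge_mip_set`: per-side strips (x, y, z arrays), per-side
#'   lists of block MIP images, block centers, geometry.
#' @export
extract_edge_mips <- function(tile, edge_fraction = 0.10, block_size = 32L) {
  if (block_size < 1) stop("extract_edge_mips: block_size must be >= 1",
                           call. = FALSE)
  if (edge_fraction <= 0 || edge_fraction > 0.5)
    stop("extract_edge_mips: edge_fraction must be in (0, 0.5]",
         call. = FALSE)
  d <- tile$dim
  wx <- max(1L, as.integer(round(edge_fraction * d[1])))
  wy <- max(1L, as.integer(round(edge_fraction * d[2])))
  nb <- as.integer(ceiling(d[3] / block_size))
  strips <- list(left = array(0, c(wx, d[2], d[3])),
                 right = array(0, c(wx, d[2], d[3])),
                 top = array(0, c(d[1], wy, d[3])),
                 bottom = array(0, c(d[1], wy, d[3])))
  mips <- list(left = vector("list", nb), right = vector("list", nb),
               top = vector("list", nb), bottom = vector("list", nb))
  for (b in seq_len(nb)) {
    slab <- read_chunk(tile, b)
    z0 <- (b - 1L) * block_size
    zr <- z0 + seq_len(dim(slab)[3])
    strips$left[, , zr] <- slab[seq_len(wx), , , drop = FALSE]
    strips$right[, , zr] <- slab[d[1] - wx + seq_len(wx), , , drop = FALSE]
    strips$top[, , zr] <- slab[, seq_len(wy), , drop = FALSE]
    strips$bottom[, , zr] <- slab[, d[2] - wy + seq_len(wy), , drop = FALSE]
    for (s in names(mips)) {
      m <- strips[[s]][, , zr[1]]
      for (k in zr[-1]) m <- pmax(m, strips[[s]][, , k])
      mips[[s]][[b]] <- m
    }
  }
  structure(list(col = tile$col, row = tile$row, dim = d,
                 edge_fraction = edge_fraction, block_size = block_size,
                 n_blocks = nb, strip_width = c(wx, wy),
                 block_centers = vapply(seq_len(nb), function(b) {
                   z0 <- (b - 1L) * block_size
                   z1 <- min(b * block_size, d[3]) - 1L
                   (z0 + z1) / 2
                 }, numeric(1)),
                 strips = strips, mips = mips),
            class = "edge_mip_set")
}

mip_key <- function(col, row) sprintf("c%d_r%d", col, row)

# MIP of a side strip over an arbitrary z window
window_mip <- function(mipset, side, z0, z1) {
  s <- mipset$strips[[side]]
  m <- s[, , z0]
  if (z1 > z0) for (k in (z0 + 1L):z1) m <- pmax(m, s[, , k])
  m
}

# scalar 1-D shift between two profile matrices (feature x z), NCC over
# integer shifts, ties toward `prefer`
profile_shift <- function(pa, pb, search, prefer = 0L) {
  nz <- min(ncol(pa), ncol(pb))
  best <- -Inf; bs <- prefer
  cand <- order(abs(seq(-search, search) - 0))
  for (s in seq(-search, search)) {
    za <- max(1, 1 + s):min(nz, nz + s)
    zb <- za - s
    v <- ncc(as.numeric(pa[, za]), as.numeric(pb[, zb]))
    if (v > best + 1e-12 ||
        (v > best - 1e-12 && abs(s - prefer) < abs(bs - prefer))) {
      best <- v; bs <- s
    }
  }
  structure(bs, score = best)
}

#' Align z coordinates across tile columns
#'
#' Correlates the facing left/right edge strips of horizontally adjacent
#' columns along z (strips averaged over their width, all rows stacked)
#' and chains the pairwise z shifts, anchoring column 1 at 0.
#'
#' @param mipsets named list of [extract_edge_mips()] results for all tiles.
#' @param search_range maximum |z| shift considered (slices).
#' @param on_out_of_range `"error"` or `"clip"` when the best shift hits
#'   the search bound.
#' @return integer z offset per column (column 1 is 0).
#' @export
align_z_columns <- function(mipsets, search_range = 8L,
                            on_out_of_range = c("error", "clip")) {
  on_out_of_range <- match.arg(on_out_of_range)
  cols <- sort(unique(vapply(mipsets, `[[`, numeric(1), "col")))
  rows <- sort(unique(vapply(mipsets, `[[`, numeric(1), "row")))
  if (length(cols) < 2) return(stats::setNames(0L, mip_key(cols, rows[1])))
  if (all(vapply(mipsets, function(m)
    max(abs(m$strips$right)) == 0 && max(abs(m$strips$left)) == 0,
    logical(1))))
    stop("align_z_columns: degenerate signal (all-zero edge strips)",
         call. = FALSE)
  dz <- integer(length(cols))
  for (ci in seq_len(length(cols) - 1)) {
    pa <- do.call(rbind, lapply(rows, function(r) {
      s <- mipsets[[mip_key(cols[ci], r)]]$strips$right
      apply(s, c(2, 3), mean)
    }))
    pb <- do.call(rbind, lapply(rows, function(r) {
      s <- mipsets[[mip_key(cols[ci + 1], r)]]$strips$left
      apply(s, c(2, 3), mean)
    }))
    if (stats::sd(pa) == 0 || stats::sd(pb) == 0)
      stop("align_z_columns: degenerate signal in column pair ", ci,
           call. = FALSE)
    s <- profile_shift(pa, pb, search_range)
    if (abs(s) >= search_range) {
      if (on_out_of_range == "error")
        stop("align_z_columns: shift at search bound for column pair ", ci,
             call. = FALSE)
      warning("align_z_columns: shift clipped at search bound",
              call. = FALSE)
    }
    dz[ci + 1] <- dz[ci] + as.integer(s)
  }
  stats::setNames(dz, paste0("c", cols))
}

# Overlap-patch extraction between adjacent tiles. For a horizontal pair
# (axis 1, b right of a) the top and bottom strips of both tiles cover the
# full overlap zone, so cropping them at the nominal stride yields two
# equal-size patches whose content shift equals offset(b) - offset(a).
# `img_a`/`img_b` are matching side images (block MIP or single slice).
overlap_patches <- function(ma, mb, axis, stride, img_a, img_b) {
  if (axis == 1L) {
    tw <- ma$dim[1]
    ov <- tw - stride[1]
    if (ov < 3L) return(NULL)
    list(a = img_a[(stride[1] + 1L):tw, , drop = FALSE],
         b = img_b[seq_len(ov), , drop = FALSE])
  } else {
    th <- ma$dim[2]
    ov <- th - stride[2]
    if (ov < 3L) return(NULL)
    list(a = img_a[, (stride[2] + 1L):th, drop = FALSE],
         b = img_b[, seq_len(ov), drop = FALSE])
  }
}

# sides whose strips straddle the overlap zone of an adjacent pair
pair_sides <- function(axis) if (axis == 1L) c("top", "bottom") else
  c("left", "right")

# integer NCC search for the content shift delta = offset(b) - offset(a)
# (pb(i) = pa(i + delta)), with parabolic sub-voxel refinement per axis;
# ties broken toward `prefer`
patch_shift <- function(pa, pb, search, prefer = c(0, 0), subpixel = TRUE) {
  if (stats::sd(pa) == 0 || stats::sd(pb) == 0) return(NULL)
  best <- -Inf; bs <- c(0L, 0L)
  scores <- matrix(NA_real_, 2 * search + 1, 2 * search + 1)
  for (dx in -search:search) for (dy in -search:search) {
    ov <- shifted_overlap(pa, pb, c(dx, dy))
    if (is.null(ov)) next
    v <- ncc(ov$a, ov$b)
    scores[dx + search + 1, dy + search + 1] <- v
    if (v > best + 1e-12 ||
        (v > best - 1e-12 &&
           sum(abs(c(dx, dy) - prefer)) < sum(abs(bs - prefer)))) {
      best <- v; bs <- c(dx, dy)
    }
  }
  if (!is.finite(best)) return(NULL)
  out <- as.numeric(bs)
  if (subpixel) {
    for (ax in 1:2) {
      i <- bs[1] + search + 1; j <- bs[2] + search + 1
      trip <- if (ax == 1) c(i - 1, i, i + 1) else c(j - 1, j, j + 1)
      ok <- trip >= 1 & trip <= 2 * search + 1
      if (!all(ok)) next
      y <- if (ax == 1) scores[trip, j] else scores[i, trip]
      if (any(is.na(y))) next
      den <- y[1] - 2 * y[2] + y[3]
      if (is.finite(den) && abs(den) > 1e-12) {
        delta <- 0.5 * (y[1] - y[3]) / den
        if (abs(delta) < 1) out[ax] <- out[ax] + delta
      }
    }
  }
  structure(out, score = best)
}

adjacent_pairs <- function(cols, rows) {
  pairs <- list()
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    if (c < cols) pairs[[length(pairs) + 1L]] <-
        list(a = c(c, r), b = c(c + 1L, r), axis = 1L)
    if (r < rows) pairs[[length(pairs) + 1L]] <-
        list(a = c(c, r), b = c(c, r + 1L), axis = 2L)
  }
  pairs
}

#' Align x/y tile coordinates from edge MIPs
#'
#' Estimates pairwise (dx, dy) offsets between adjacent tiles per z block
#' by normalized cross-correlation of the facing strip MIPs (parabolic
#' sub-voxel peak refinement, ties toward zero), then reconciles them into
#' per-tile offsets by least squares over the tile adjacency graph with
#' the first tile anchored at 0.
#'
#' @param mipsets named list of [extract_edge_mips()] results.
#' @param z_offsets per-column z offsets from [align_z_columns()].
#' @param grid the [tile_grid()] (for strides and geometry).
#' @param search maximum |shift| in voxels for the pairwise correlation.
#' @return a `tile_offsets` object holding per-tile per-block (dx, dy),
#'   per-tile dz, block centers and audit information.
#' @export
align_xy <- function(mipsets, z_offsets, grid, search = 8L) {
  cols <- grid$cols; rows <- grid$rows
  keys <- vapply(mipsets, function(m) mip_key(m$col, m$row), character(1))
  names(mipsets) <- keys
  nb <- mipsets[[1]]$n_blocks
  pairs <- adjacent_pairs(cols, rows)
  tile_index <- function(c, r) (r - 1L) * cols + c
  nt <- cols * rows
  if (nt > 1 && length(pairs) == 0)
    stop("align_xy: disconnected tile graph", call. = FALSE)
  dz_of <- function(c) as.numeric(z_offsets[paste0("c", c)])
  Z <- mipsets[[1]]$dim[3]
  block_off <- lapply(seq_len(nt), function(i) matrix(0, nb, 2))
  solve_ls <- function(rowsL, rhs) {
    # anchor tile 1 at zero
    for (ax in 1:2) {
      coefrow <- numeric(2 * nt)
      coefrow[ax] <- 1e3
      rowsL[[length(rowsL) + 1L]] <- coefrow
      rhs[[length(rhs) + 1L]] <- 0
    }
    sol <- stats::lm.fit(do.call(rbind, rowsL), unlist(rhs))$coefficients
    sol[is.na(sol)] <- 0
    sol
  }
  pair_row <- function(ia, ib, ax) {
    coefrow <- numeric(2 * nt)
    coefrow[2 * (ib - 1) + ax] <- 1
    coefrow[2 * (ia - 1) + ax] <- -1
    coefrow
  }
  for (b in seq_len(nb)) {
    z0 <- (b - 1L) * mipsets[[1]]$block_size + 1L
    z1 <- min(b * mipsets[[1]]$block_size, Z)
    # gather the overlap patches of every adjacency once
    plist <- list()
    for (p in pairs) {
      ka <- mip_key(p$a[1], p$a[2]); kb <- mip_key(p$b[1], p$b[2])
      ma <- mipsets[[ka]]; mb <- mipsets[[kb]]
      ia <- tile_index(p$a[1], p$a[2]); ib <- tile_index(p$b[1], p$b[2])
      dzr <- dz_of(p$a[1]) - dz_of(p$b[1])
      zb0 <- max(1L, z0 + dzr); zb1 <- min(Z, z1 + dzr)
      if (zb1 <= zb0) next
      fps <- list()
      for (side in pair_sides(p$axis)) {
        fp <- overlap_patches(ma, mb, p$axis, grid$stride,
                              window_mip(ma, side, z0, z1),
                              window_mip(mb, side, zb0, zb1))
        if (!is.null(fp)) fps[[length(fps) + 1L]] <- fp
      }
      # drop near-noise sides: block MIPs of background strips decorrelate
      # under intra-block drift and would pollute the solve
      if (length(fps) > 1) {
        sds <- vapply(fps, function(fp) stats::sd(fp$a), numeric(1))
        fps <- fps[sds >= 0.3 * max(sds)]
      }
      if (length(fps) > 0)
        plist[[length(plist) + 1L]] <- list(ia = ia, ib = ib, fps = fps)
    }
    # pass 1: wide correlation search, least-squares reconciliation with
    # residual trimming (adjacent tiles can be displaced beyond what their
    # shared strip support can measure; such estimates are inconsistent
    # with the rest of the graph and get dropped)
    ests <- list()
    for (pp in plist) {
      for (fp in pp$fps) {
        sh <- patch_shift(fp$a, fp$b, search)
        if (is.null(sh) || attr(sh, "score") < 0.2 ||
            any(abs(sh) >= search - 2)) next
        ests[[length(ests) + 1L]] <- list(ia = pp$ia, ib = pp$ib, sh = sh)
      }
    }
    if (length(ests) == 0) {
      if (nt > 1) stop("align_xy: no usable pairwise estimates in block ", b,
                       call. = FALSE)
      next
    }
    build_rows <- function(es) {
      rowsL <- list(); rhs <- list()
      for (e in es) for (ax in 1:2) {
        rowsL[[length(rowsL) + 1L]] <- pair_row(e$ia, e$ib, ax)
        rhs[[length(rhs) + 1L]] <- e$sh[ax]
      }
      list(rowsL = rowsL, rhs = rhs)
    }
    br <- build_rows(ests)
    sol <- solve_ls(br$rowsL, br$rhs)
    resid <- vapply(ests, function(e)
      max(abs(e$sh - (sol[2 * (e$ib - 1) + 1:2] -
                        sol[2 * (e$ia - 1) + 1:2]))), numeric(1))
    keep <- resid <= 3
    if (any(keep) && !all(keep)) {
      br <- build_rows(ests[keep])
      sol <- solve_ls(br$rowsL, br$rhs)
    }
    # pass 2: re-correlate each adjacency in a narrow window around the
    # pass-1 solution (large relative shifts leave little patch support,
    # so the wide search is only trusted as initialization)
    rowsL <- list(); rhs <- list()
    for (pp in plist) {
      prior <- sol[2 * (pp$ib - 1) + 1:2] - sol[2 * (pp$ia - 1) + 1:2]
      sh <- snap_pair_shift(pp$fps, prior, window = 3L, subpixel = TRUE)
      if (is.null(sh)) next
      for (ax in 1:2) {
        rowsL[[length(rowsL) + 1L]] <- pair_row(pp$ia, pp$ib, ax)
        rhs[[length(rhs) + 1L]] <- sh[ax]
      }
    }
    if (length(rowsL) > 0) sol <- solve_ls(rowsL, rhs)
    for (i in seq_len(nt))
      block_off[[i]][b, ] <- sol[2 * (i - 1) + 1:2]
  }
  dz_tile <- vapply(seq_len(nt), function(i) {
    c_i <- (i - 1L) %% cols + 1L
    as.numeric(z_offsets[paste0("c", c_i)])
  }, numeric(1))
  structure(list(block = block_off, dz = dz_tile,
                 block_centers = mipsets[[1]]$block_centers,
                 block_size = mipsets[[1]]$block_size,
                 zcount = mipsets[[1]]$dim[3],
                 cols = cols, rows = rows, slice = NULL,
                 fit_residual = NULL),
            class = "tile_offsets")
}

#' Refine block offsets to per-slice offsets by curve fitting
#'
#' Fits a smooth curve (smoothing spline with GCV when >= 4 blocks, else a
#' straight line) through each tile's block offsets versus block-center z
#' and evaluates it at every slice. When the edge strips are supplied, the
#' fitted per-slice offsets are additionally snapped to integers by
#' per-slice correlation of facing edge strips within +-1 voxel of the
#' curve (tile placement is on the voxel grid, so integer-exact offsets
#' are what fusion consumes).
#'
#' @param offsets a `tile_offsets` from [align_xy()].
#' @param model `"spline"` or `"linear"`.
#' @param mipsets optional named list of [extract_edge_mips()] results
#'   enabling the per-slice integer snap.
#' @param grid the [tile_grid()]; required with `mipsets`.
#' @return `offsets` with a per-tile `slice` matrix (zcount x 2) and the
#'   curve-fit residuals filled in.
#' @export
refine_slice_offsets <- function(offsets, model = c("spline", "linear"),
                                 mipsets = NULL, grid = NULL) {
  model <- match.arg(model)
  nb <- length(offsets$block_centers)
  zs <- seq_len(offsets$zcount) - 1L
  nt <- length(offsets$block)
  slice <- vector("list", nt)
  resid <- numeric(nt)
  for (i in seq_len(nt)) {
    bo <- offsets$block[[i]]
    if (nb == 1L) {
      warning("refine_slice_offsets: single block; constant extension",
              call. = FALSE)
      slice[[i]] <- cbind(rep(bo[1, 1], length(zs)),
                          rep(bo[1, 2], length(zs)))
      next
    }
    fitax <- function(y) {
      if (model == "spline" && nb >= 4L) {
        sp <- stats::smooth.spline(offsets$block_centers, y, cv = FALSE,
                                   all.knots = TRUE)
        list(pred = stats::predict(sp, zs)$y,
             res = max(abs(stats::predict(sp, offsets$block_centers)$y - y)))
      } else {
        co <- stats::coef(stats::lm(y ~ offsets$block_centers))
        list(pred = co[1] + co[2] * zs,
             res = max(abs(co[1] + co[2] * offsets$block_centers - y)))
      }
    }
    fx <- fitax(bo[, 1]); fy <- fitax(bo[, 2])
    slice[[i]] <- cbind(fx$pred, fy$pred)
    resid[i] <- max(fx$res, fy$res)
  }
  offsets$slice <- slice
  offsets$fit_residual <- resid
  if (!is.null(mipsets)) {
    stopifnot(!is.null(grid))
    # two snap passes: the second runs with the first pass's integer
    # solution as prior everywhere, pulling in stragglers whose initial
    # curve-fit prior was off
    offsets <- snap_slice_offsets(offsets, mipsets, grid)
    offsets <- snap_slice_offsets(offsets, mipsets, grid)
  }
  offsets
}

# per-slice integer snap: pairwise strip correlation within +-1 voxel of
# the fitted curve, least-squares per slice, rounded
snap_slice_offsets <- function(offsets, mipsets, grid) {
  keys <- vapply(mipsets, function(m) mip_key(m$col, m$row), character(1))
  names(mipsets) <- keys
  cols <- grid$cols; rows <- grid$rows
  nt <- cols * rows
  tile_index <- function(c, r) (r - 1L) * cols + c
  pairs <- adjacent_pairs(cols, rows)
  Z <- offsets$zcount
  # solve per world slice: tile i contributes its slice w - dz_i, so that
  # every equation in one solve describes the same physical plane
  wrange <- (1 + min(offsets$dz)):(Z + max(offsets$dz))
  # center-outward order: boundary slices (where parts of the grid have no
  # data and the gauge is weak) inherit continuity from solved neighbors
  wc <- stats::median(wrange)
  wrange <- wrange[order(abs(wrange - wc))]
  snapped <- matrix(FALSE, nt, Z)
  # prior for a tile's offset at slice z: the already-snapped neighbor
  # toward the stack center when available (offsets drift by at most one
  # voxel per slice), else the fitted curve
  prior_of <- function(i, z, w) {
    nz <- z + sign(wc - w)
    if (nz >= 1 && nz <= Z && snapped[i, nz])
      offsets$slice[[i]][nz, ]
    else offsets$slice[[i]][z, ]
  }
  for (w in wrange) {
    zi <- w - offsets$dz
    rowsL <- list(); rhs <- list()
    for (p in pairs) {
      ia <- tile_index(p$a[1], p$a[2]); ib <- tile_index(p$b[1], p$b[2])
      za <- zi[ia]; zb <- zi[ib]
      if (za < 1 || za > Z || zb < 1 || zb > Z) next
      ma <- mipsets[[mip_key(p$a[1], p$a[2])]]
      mb <- mipsets[[mip_key(p$b[1], p$b[2])]]
      prior <- prior_of(ib, zb, w) - prior_of(ia, za, w)
      fps <- list()
      for (side in pair_sides(p$axis)) {
        fp <- overlap_patches(ma, mb, p$axis, grid$stride,
                              ma$strips[[side]][, , za],
                              mb$strips[[side]][, , zb])
        if (!is.null(fp)) fps[[length(fps) + 1L]] <- fp
      }
      sh <- snap_pair_shift(fps, prior)
      if (is.null(sh)) next
      # weight by match quality: exact shared-content matches score ~1,
      # thin ambiguous slivers much lower
      wgt <- max(0, (attr(sh, "score") - 0.5) / 0.5)^2
      if (wgt <= 0) next
      for (ax in 1:2) {
        coefrow <- numeric(2 * nt)
        coefrow[2 * (ib - 1) + ax] <- wgt
        coefrow[2 * (ia - 1) + ax] <- -wgt
        rowsL[[length(rowsL) + 1L]] <- coefrow
        rhs[[length(rhs) + 1L]] <- wgt * sh[ax]
      }
    }
    if (length(rowsL) == 0) next
    # weak prior keeps the gauge at the fitted curves; strong anchor at tile 1
    for (i in seq_len(nt)) {
      if (zi[i] < 1 || zi[i] > Z) next
      nb <- c(zi[i] - 1L, zi[i] + 1L)
      nb <- nb[nb >= 1 & nb <= Z]
      nb <- nb[snapped[i, nb]]
      pw <- if (length(nb) > 0) 0.4 else 0.05
      pv <- if (length(nb) > 0)
        colMeans(offsets$slice[[i]][nb, , drop = FALSE]) else
          offsets$slice[[i]][zi[i], ]
      for (ax in 1:2) {
        coefrow <- numeric(2 * nt)
        coefrow[2 * (i - 1) + ax] <- if (i == 1L) 1e3 else pw
        rowsL[[length(rowsL) + 1L]] <- coefrow
        rhs[[length(rhs) + 1L]] <- if (i == 1L) 0 else pw * pv[ax]
      }
    }
    A <- do.call(rbind, rowsL)
    y <- unlist(rhs)
    sol <- stats::lm.fit(A, y)$coefficients
    sol[is.na(sol)] <- 0
    for (i in seq_len(nt)) {
      if (zi[i] < 1 || zi[i] > Z) next
      offsets$slice[[i]][zi[i], ] <- round(sol[2 * (i - 1) + 1:2])
      snapped[i, zi[i]] <- TRUE
    }
  }
  offsets
}

# best 2-D shift within +-window of a real-valued prior, scored jointly
# over a list of patch pairs (both strip sides of one adjacency); optional
# parabolic sub-voxel refinement
snap_pair_shift <- function(fps, prior, window = 2L, subpixel = FALSE) {
  fps <- Filter(function(fp) stats::sd(fp$a) > 0 && stats::sd(fp$b) > 0,
                fps)
  if (length(fps) == 0) return(NULL)
  base <- round(prior)
  n <- 2L * window + 1L
  scores <- matrix(NA_real_, n, n)
  best <- -Inf; bi <- c(window + 1L, window + 1L)
  for (ddx in -window:window) for (ddy in -window:window) {
    s <- base + c(ddx, ddy)
    v <- 0; k <- 0L
    for (fp in fps) {
      ov <- shifted_overlap(fp$a, fp$b, s)
      if (is.null(ov)) next
      v <- v + ncc(ov$a, ov$b)
      k <- k + 1L
    }
    if (k == 0L) next
    v <- v / k
    scores[ddx + window + 1L, ddy + window + 1L] <- v
    better <- v > best + 1e-12 ||
      (v > best - 1e-12 &&
         sum(abs(s - prior)) < sum(abs(base + c(ddx, ddy) - prior)))
    if (better) { best <- v; bi <- c(ddx, ddy) + window + 1L }
  }
  if (!is.finite(best) || best < 0.5) return(NULL)
  out <- as.numeric(base + bi - window - 1L)
  attr(out, "score") <- best
  if (subpixel) {
    for (ax in 1:2) {
      trip <- if (ax == 1) cbind(bi[1] + (-1:1), bi[2]) else
        cbind(bi[1], bi[2] + (-1:1))
      if (any(trip < 1 | trip > n)) next
      y <- scores[trip]
      if (any(is.na(y))) next
      den <- y[1] - 2 * y[2] + y[3]
      if (is.finite(den) && abs(den) > 1e-12) {
        delta <- 0.5 * (y[1] - y[3]) / den
        if (abs(delta) < 1) out[ax] <- out[ax] + delta
      }
    }
  }
  out
}

# overlap of pa and pb where pb's content is displaced by s relative to pa:
# pb(i) = pa(i + s)  =>  compare pa[i + s] with pb[i]
shifted_overlap <- function(pa, pb, s) {
  d <- dim(pa)
  if (abs(s[1]) >= d[1] - 1 || abs(s[2]) >= d[2] - 1) return(NULL)
  xa <- max(1, 1 + s[1]):min(d[1], d[1] + s[1])
  ya <- max(1, 1 + s[2]):min(d[2], d[2] + s[2])
  if (length(xa) < 2 || length(ya) < 2) return(NULL)
  list(a = pa[xa, ya], b = pb[xa - s[1], ya - s[2]])
}

#' Fuse tiles into a single volume
#'
#' Places every tile at its nominal grid position plus its solved offsets
#' (per slice when available) and blends overlaps. This is the second and
#' last pass over raw data: each chunk is read exactly once here.
#' `"linear_feather"` ramps weights across the overlap zone so
#' single-coverage voxels reproduce their unique source tile exactly;
#' `"max"` takes the voxel-wise maximum.
#'
#' @param grid a [tile_grid()].
#' @param offsets a `tile_offsets` with slice offsets (see
#'   [refine_slice_offsets()]); block offsets are used as constants if no
#'   slice refinement was run.
#' @param blend `"linear_feather"` or `"max"`.
#' @return an [image_volume] covering the bounding box of all placed
#'   tiles.
#' @export
fuse <- function(grid, offsets, blend = c("linear_feather", "max")) {
  blend <- match.arg(blend)
  tiles <- grid$tiles
  nt <- grid$cols * grid$rows
  if (length(offsets$block) < nt || is.null(offsets$dz))
    stop("fuse: offsets missing for some tiles", call. = FALSE)
  d <- grid$tile_dim
  Z <- d[3]
  # per-slice integer offsets for every tile
  sl <- vector("list", nt)
  for (i in seq_len(nt)) {
    s <- if (!is.null(offsets$slice)) offsets$slice[[i]] else {
      nearest <- vapply(seq_len(Z) - 1L, function(z)
        which.min(abs(offsets$block_centers - z)), integer(1))
      offsets$block[[i]][nearest, , drop = FALSE]
    }
    sl[[i]] <- round(s)
  }
  place <- function(i) {
    c_i <- (i - 1L) %% grid$cols + 1L
    r_i <- (i - 1L) %/% grid$cols + 1L
    c((c_i - 1L) * grid$stride[1], (r_i - 1L) * grid$stride[2])
  }
  xr <- range(unlist(lapply(seq_len(nt), function(i)
    place(i)[1] + range(sl[[i]][, 1]) + c(0, d[1] - 1))))
  yr <- range(unlist(lapply(seq_len(nt), function(i)
    place(i)[2] + range(sl[[i]][, 2]) + c(0, d[2] - 1))))
  zr <- range(unlist(lapply(seq_len(nt), function(i)
    offsets$dz[i] + c(0, Z - 1))))
  ox <- xr[1]; oy <- yr[1]; oz <- zr[1]
  out <- array(0, c(diff(xr) + 1L, diff(yr) + 1L, diff(zr) + 1L))
  acc <- array(0, dim(out))
  ncov <- array(0L, dim(out))
  last <- array(0, dim(out))
  fw <- pmax(1L, c(d[1] - grid$stride[1], d[2] - grid$stride[2]))
  wx <- pmin(1, (pmin(seq_len(d[1]), d[1] + 1 - seq_len(d[1]))) / fw[1])
  wy <- pmin(1, (pmin(seq_len(d[2]), d[2] + 1 - seq_len(d[2]))) / fw[2])
  w2 <- outer(wx, wy)
  for (i in seq_len(nt)) {
    tl <- tiles[[mip_key((i - 1L) %% grid$cols + 1L,
                         (i - 1L) %/% grid$cols + 1L)]]
    p0 <- place(i)
    for (b in seq_len(tl$n_blocks)) {
      slab <- read_chunk(tl, b)
      z0 <- (b - 1L) * grid$block_size
      for (zz in seq_len(dim(slab)[3])) {
        z <- z0 + zz
        xs <- p0[1] + sl[[i]][z, 1] - ox + seq_len(d[1])
        ys <- p0[2] + sl[[i]][z, 2] - oy + seq_len(d[2])
        zp <- offsets$dz[i] + z - oz
        if (blend == "max") {
          out[xs, ys, zp] <- pmax(out[xs, ys, zp], slab[, , zz])
          acc[xs, ys, zp] <- 1
        } else {
          out[xs, ys, zp] <- out[xs, ys, zp] + w2 * slab[, , zz]
          acc[xs, ys, zp] <- acc[xs, ys, zp] + w2
          ncov[xs, ys, zp] <- ncov[xs, ys, zp] + 1L
          last[xs, ys, zp] <- slab[, , zz]
        }
      }
    }
  }
  if (blend != "max") {
    nz <- acc > 0
    out[nz] <- out[nz] / acc[nz]
    # single-coverage voxels reproduce their unique source exactly
    s1 <- ncov == 1L
    out[s1] <- last[s1]
  }
  image_volume(out, spacing = grid$spacing,
               origin = c(ox, oy, oz) * grid$spacing)
}

#' Run the full stitching pipeline
#'
#' Pass 1 collects edge strips and block MIPs; z columns are aligned, x/y
#' block offsets solved and refined to per-slice offsets; pass 2 fuses.
#'
#' @inheritParams extract_edge_mips
#' @inheritParams align_z_columns
#' @inheritParams fuse
#' @param grid a [tile_grid()].
#' @param snap snap per-slice offsets to integers using the edge strips.
#' @return list(volume, offsets, mipsets).
#' @export
stitch_tiles <- function(grid, edge_fraction = 0.10, block_size = 32L,
                         search_range = 8L, blend = "linear_feather",
                         snap = TRUE) {
  mipsets <- lapply(grid$tiles, extract_edge_mips,
                    edge_fraction = edge_fraction, block_size = block_size)
  zoff <- align_z_columns(mipsets, search_range = search_range)
  off <- align_xy(mipsets, zoff, grid, search = search_range)
  off <- refine_slice_offsets(off, "spline",
                              mipsets = if (snap) mipsets else NULL,
                              grid = grid)
  vol <- fuse(grid, off, blend = blend)
  list(volume = vol, offsets = off, mipsets = mipsets)
}
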