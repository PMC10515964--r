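# small shared helpers

# run code with a fixed RNG state, restoring the caller's state afterwards
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Matrix exponential by scaling and squaring with a Taylor series; adequate
# for the well-conditioned 4x4 affines handled here.
mat_expm <- function(A, order = 12L) {
  nrm <- max(abs(A))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
  As <- A / 2^s
  E <- diag(nrow(A))
  term <- diag(nrow(A))
  for (k in seq_len(order)) {
    term <- term %*% As / k
    E <- E + term
  }
  for (i in seq_len(s)) E <- E %*% E
  E
}

# Matrix logarithm by inverse scaling and squaring: repeated square roots
# (Denman-Beavers) until close to I, then a Taylor log.
mat_logm <- function(A, sqrt_iters = 30L) {
  n <- nrow(A)
  k <- 0L
  X <- A
  while (max(abs(X - diag(n))) > 0.25 && k < 30L) {
    Y <- X
    Z <- diag(n)
    for (i in seq_len(sqrt_iters)) {
      Yn <- 0.5 * (Y + solve(Z))
      Z <- 0.5 * (Z + solve(Y))
      Y <- Yn
    }
    X <- Y
    k <- k + 1L
  }
  M <- X - diag(n)
  L <- matrix(0, n, n)
  term <- diag(n)
  for (j in 1:16) {
    term <- term %*% M
    L <- L + ((-1)^(j + 1) / j) * term
  }
  L * 2^k
}

# normalized cross-correlation of two equal-length vectors
ncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  d <- sqrt(sum(a^2) * sum(b^2))
  if (d == 0) return(0)
  sum(a * b) / d
}

# N-D phase/normalized cross-correlation shift estimate between equal-dim
# arrays, with parabolic sub-voxel peak refinement. Returns shift such that
# moving displaced by -shift best matches fixed (i.e. fixed(x) ~ moving(x - shift)).
cross_correlate_shift <- function(fixed, moving, max_shift = NULL,
                                  subpixel = TRUE) {
  d <- dim(fixed)
  if (is.null(d)) { d <- length(fixed); dim(fixed) <- d; dim(moving) <- d }
  stopifnot(all(dim(moving) == d))
  f <- fixed - mean(fixed)
  m <- moving - mean(moving)
  Ff <- stats::fft(f)
  Fm <- stats::fft(m)
  cc <- Re(stats::fft(Ff * Conj(Fm), inverse = TRUE))
  dim(cc) <- d
  nd <- length(d)
  # restrict to allowed circular shifts
  if (!is.null(max_shift)) {
    ms <- rep_len(max_shift, nd)
    for (ax in seq_len(nd)) {
      idx <- seq_len(d[ax]) - 1L
      shift_ax <- ifelse(idx > d[ax] / 2, idx - d[ax], idx)
      keep <- abs(shift_ax) <= ms[ax]
      cc <- apply_mask_axis(cc, ax, keep)
    }
  }
  peak <- which(cc == max(cc))
  # deterministic tie-break toward zero shift
  coords <- arrayInd(peak, d) - 1L
  shifts <- coords
  for (ax in seq_len(nd))
    shifts[, ax] <- ifelse(coords[, ax] > d[ax] / 2, coords[, ax] - d[ax],
                           coords[, ax])
  best <- order(rowSums(abs(shifts)))[1]
  sh <- shifts[best, ]
  if (subpixel) {
    for (ax in seq_len(nd)) {
      ctr <- coords[best, ]
      at <- function(off) {
        p <- ctr
        p[ax] <- (p[ax] + off) %% d[ax]
        cc[matrix(p + 1L, 1L)]
      }
      y0 <- at(-1L); y1 <- at(0L); y2 <- at(1L)
      den <- y0 - 2 * y1 + y2
      if (is.finite(den) && abs(den) > 1e-12) {
        delta <- 0.5 * (y0 - y2) / den
        if (abs(delta) < 1) sh[ax] <- sh[ax] + delta
      }
    }
  }
  sh
}

apply_mask_axis <- function(x, ax, keep) {
  d <- dim(x)
  idx <- rep(list(quote(expr = )), length(d))
  idx[[ax]] <- which(!keep)
  if (length(idx[[ax]]) > 0) {
    x <- do.call(`[<-`, c(list(x), idx, list(value = -Inf)))
  }
  x
}
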