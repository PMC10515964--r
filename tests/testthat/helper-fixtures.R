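# shared fixtures; everything is generated in code, nothing read from disk

small_phantom <- function(shape = c(24, 24, 24), seed = 1, ...) {
  make_phantom(shape, seed = seed, ...)
}

rand_volume <- function(dim = c(8, 8, 8), seed = 1, spacing = c(1, 1, 1)) {
  image_volume(array(with_seed_test(seed, stats::runif(prod(dim))), dim),
               spacing = spacing)
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  force(code)
}

# mean per-voxel displacement magnitude of a transform, in voxels
mean_disp_vox <- function(t, g, mask = NULL) {
  u <- devatlas:::total_displacement_on(t, g)
  n <- sqrt(apply(u^2, 1:3, sum)) / mean(g$spacing)
  if (is.null(mask)) mean(n) else mean(n[mask])
}

max_disp_vox <- function(t, g, mask = NULL) {
  u <- devatlas:::total_displacement_on(t, g)
  n <- sqrt(apply(u^2, 1:3, sum)) / mean(g$spacing)
  if (is.null(mask)) max(n) else max(n[mask])
}

centroid_of <- function(vol) {
  d <- dim(vol$data)
  idx <- arrayInd(seq_len(prod(d)), d) - 1L
  w <- as.numeric(vol$data)
  colSums(idx * w) / sum(w)
}

tmp_dir <- local({
  d <- NULL
  function() {
    if (is.null(d)) d <<- tempfile("devatlas-test-")
    if (!dir.exists(d)) dir.create(d, recursive = TRUE)
    d
  }
})
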