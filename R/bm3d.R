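#' BM3D denoising
#'
#' Two-pass block-matching with collaborative 3D transform-domain
#' filtering, applied to every offset image independently. Pass one
#' groups similar blocks from a search window, applies an orthonormal 3D
#' discrete cosine transform and hard-thresholds coefficients below
#' `2.7 sigma` to form the basic estimate; pass two re-matches on the
#' basic estimate and applies empirical Wiener shrinkage to the noisy
#' groups. Aggregation is weighted by retained-coefficient count
#' (respectively Wiener energy). The benchmark naming convention is
#' `BM3D WS_<window>_BS_<block>`.
#'
#' @param vol a [cest_volume()].
#' @param window_size search-window size N (must exceed `block_size`).
#' @param block_size 2D block size B.
#' @param sigma noise level; defaults to [estimate_sigma()] of `vol`.
#' @param step reference-block stride.
#' @param max_group maximum number of blocks per group.
#' @param lambda hard-threshold multiplier (canonical 2.7).
#' @return the denoised [cest_volume()].
#' @export
bm3d_denoise <- function(vol, window_size = 11L, block_size = 4L,
                         sigma = NULL, step = 3L, max_group = 16L,
                         lambda = 2.7) {
  stopifnot(inherits(vol, "cest_volume"))
  if (block_size >= window_size)
    stop("block_size must be smaller than window_size")
  d <- dim(vol$data)
  stopifnot(block_size <= min(d[1], d[2]))
  if (is.null(sigma)) sigma <- estimate_sigma(vol)
  out <- vol$data
  for (o in seq_len(vol$dyn))
    out[, , o] <- cpp_bm3d(vol$data[, , o], as.integer(block_size),
                           as.integer(window_size), sigma,
                           as.integer(step), as.integer(max_group), lambda)
  update_data(vol, out)
}

#' Benchmark method label of a BM3D configuration
#' @param window_size,block_size BM3D sizes.
#' @return e.g. `"BM3D WS_11_BS_4"`.
#' @export
bm3d_method_name <- function(window_size, block_size) {
  sprintf("BM3D WS_%d_BS_%d", window_size, block_size)
}
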