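#' Non-local means denoising
#'
#' Filters every offset image independently: each pixel becomes a
#' weighted average of the pixels in its search ("big") window, the
#' weights a Gaussian of the mean squared difference between local
#' ("small") patches, with the usual noise-variance offset
#' `max(d2 - 2 sigma^2, 0)`. The benchmark naming convention is
#' `NLM BW_<big>_SW_<small>`.
#'
#' @param vol a [cest_volume()].
#' @param big_window odd search-window size (default 21).
#' @param small_window odd patch size (default 5), smaller than
#'   `big_window`.
#' @param h filtering strength; defaults to `0.8 * sigma`.
#' @param sigma noise level; defaults to [estimate_sigma()] of `vol`.
#' @return the denoised [cest_volume()].
#' @export
nlm_denoise <- function(vol, big_window = 21L, small_window = 5L,
                        h = NULL, sigma = NULL) {
  stopifnot(inherits(vol, "cest_volume"))
  stopifnot(big_window %% 2 == 1, small_window %% 2 == 1,
            small_window < big_window)
  d <- dim(vol$data)
  if (big_window > min(d[1], d[2]))
    stop("search window larger than the image")
  if (is.null(sigma)) sigma <- estimate_sigma(vol)
  if (is.null(h)) h <- 0.8 * sigma
  h <- max(h, 1e-8)
  out <- vol$data
  for (o in seq_len(vol$dyn))
    out[, , o] <- cpp_nlm(vol$data[, , o], as.integer(big_window),
                          as.integer(small_window), h, sigma)
  update_data(vol, out)
}

#' Benchmark method label of an NLM configuration
#' @param big_window,small_window window sizes.
#' @return e.g. `"NLM BW_21_SW_5"`.
#' @export
nlm_method_name <- function(big_window, small_window) {
  sprintf("NLM BW_%d_SW_%d", big_window, small_window)
}
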