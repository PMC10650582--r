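#' Corrupt a CEST volume with k-space Gaussian noise
#'
#' Emulates thermal MR noise: every offset image is Fourier-transformed
#' (unitary normalization), independent Gaussian noise of standard
#' deviation `sigma` is added to the real and imaginary components, and
#' the image is reconstructed as the magnitude of the inverse transform.
#' With the unitary convention the image-domain complex noise has per-
#' channel standard deviation `sigma` on the normalized-signal scale, so
#' magnitude noise on bright tissue is approximately Gaussian with that
#' standard deviation and dark background becomes Rician.
#'
#' @param vol a [cest_volume()].
#' @param sigma noise level on the normalized-signal scale (the reference
#'   experiments use values in 0 to 0.25).
#' @param seed integer seed; the corruption is deterministic given it.
#' @return the corrupted [cest_volume()].
#' @examples
#' v <- cest_volume(array(1, c(16, 16, 4)), c(-2, -1, 1, 2))
#' noisy <- add_kspace_noise(v, sigma = 0.1, seed = 1)
#' @export
add_kspace_noise <- function(vol, sigma, seed = 1L) {
  stopifnot(inherits(vol, "cest_volume"), sigma >= 0)
  if (sigma == 0) return(vol)
  H <- dim(vol$data)[1]; W <- dim(vol$data)[2]
  sc <- sqrt(H * W)
  data <- with_seed(seed, {
    out <- vol$data
    for (o in seq_len(vol$dyn)) {
      ksp <- stats::fft(vol$data[, , o]) / sc
      ksp <- ksp + complex(real = stats::rnorm(H * W, 0, sigma),
                           imaginary = stats::rnorm(H * W, 0, sigma))
      out[, , o] <- Mod(stats::fft(ksp, inverse = TRUE) / sc)
    }
    out
  })
  update_data(vol, data,
              meta = modifyList(vol$meta, list(sigma = sigma, noise_seed = seed)))
}

#' Randomly crop the offset axis
#'
#' Extracts a contiguous window of `width` offsets (default 41 out of the
#' standard 50) with a uniformly random start, emulating a random
#' frequency deviation of the acquisition window. The offset axis and
#' data are cropped consistently.
#'
#' @param vol a [cest_volume()] with at least `width` offsets.
#' @param seed integer seed.
#' @param width window length (default 41).
#' @param start optional fixed start index (1-based); overrides `seed`.
#' @return the cropped [cest_volume()].
#' @export
random_offset_crop <- function(vol, seed = 1L, width = 41L, start = NULL) {
  stopifnot(inherits(vol, "cest_volume"))
  if (vol$dyn < width)
    stop(sprintf("volume has %d offsets, need at least %d", vol$dyn, width))
  if (is.null(start))
    start <- with_seed(seed, sample.int(vol$dyn - width + 1L, 1L))
  idx <- start:(start + width - 1L)
  cest_volume(vol$data[, , idx, drop = FALSE], vol$offsets_ppm[idx],
              m0 = vol$m0, mask = vol$mask,
              meta = modifyList(vol$meta, list(crop_start = start)))
}

#' Estimate the noise level of a CEST volume
#'
#' Robust wavelet-based estimator: the diagonal (HH) detail of a single-
#' level Haar decomposition of each offset image is dominated by noise on
#' piecewise-smooth images, so its median absolute deviation (scaled by
#' 1/0.6745) estimates the per-channel noise standard deviation. Only
#' coefficients whose 2x2 support lies inside the foreground mask are
#' used (background magnitude noise is Rician with a smaller spread and
#' would bias the estimate down); the estimate is averaged over offsets.
#'
#' @param vol a [cest_volume()] with at least one offset image.
#' @return estimated sigma on the normalized-signal scale.
#' @export
estimate_sigma <- function(vol) {
  stopifnot(inherits(vol, "cest_volume"))
  if (!any(vol$mask)) stop("empty mask")
  H <- dim(vol$data)[1]; W <- dim(vol$data)[2]
  io <- seq_len(H %/% 2) * 2L; jo <- seq_len(W %/% 2) * 2L
  m <- vol$mask
  keep <- m[io - 1L, jo - 1L] & m[io, jo - 1L] & m[io - 1L, jo] & m[io, jo]
  if (!any(keep)) keep[] <- TRUE
  ests <- vapply(seq_len(vol$dyn), function(o) {
    x <- vol$data[, , o]
    hh <- (x[io - 1L, jo - 1L] - x[io, jo - 1L] - x[io - 1L, jo] + x[io, jo]) / 2
    stats::median(abs(hh[keep])) / 0.6745
  }, 0)
  mean(ests)
}
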