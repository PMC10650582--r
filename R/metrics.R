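#' Peak signal-to-noise ratio of a CEST volume
#'
#' `PSNR = 10 log10(MAX^2 / MSE)` with `MAX = 1` for normalized Z-values.
#' The mean squared error is pooled over all voxels in `mask` across every
#' offset. A zero MSE returns `Inf`.
#'
#' @param clean,test [cest_volume()] objects (or plain arrays) with
#'   matching dimensions and offset axes.
#' @param mask logical matrix of voxels to pool over; default is the
#'   whole image (set to e.g. `clean$mask` to restrict to foreground).
#' @param per_voxel return an `H x W` matrix of per-voxel PSNR values
#'   (MSE pooled along the offset axis only) instead of the scalar.
#' @return PSNR in dB (scalar, or matrix when `per_voxel = TRUE`).
#' @examples
#' a <- cest_volume(array(0.5, c(8, 8, 3)), c(-1, 0, 1))
#' b <- cest_volume(array(0.6, c(8, 8, 3)), c(-1, 0, 1))
#' psnr(a, b)  # uniform error 0.1 -> 20 dB
#' @export
psnr <- function(clean, test, mask = NULL, per_voxel = FALSE) {
  x <- if (inherits(clean, "cest_volume")) clean$data else as.array(clean)
  y <- if (inherits(test, "cest_volume")) test$data else as.array(test)
  stopifnot(all(dim(x) == dim(y)))
  if (inherits(clean, "cest_volume") && inherits(test, "cest_volume"))
    stopifnot(isTRUE(all.equal(clean$offsets_ppm, test$offsets_ppm)))
  if (per_voxel) {
    mse <- apply((x - y)^2, c(1, 2), mean)
    out <- 10 * log10(1 / mse)          # Inf where the voxel MSE is 0
    if (!is.null(mask)) out[!mask] <- NA_real_
    return(out)
  }
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(x)[1:2]))
    x <- apply_mask3(x, mask); y <- apply_mask3(y, mask)
  }
  mse <- mean((x - y)^2)
  if (mse == 0) return(Inf)
  10 * log10(1 / mse)
}

apply_mask3 <- function(a, mask) {
  d <- dim(a)
  m <- matrix(a, d[1] * d[2], d[3])
  m[as.vector(mask), , drop = FALSE]
}

#' WASSR-style self-correction of a Z-spectrum
#'
#' Locates the water resonance as the minimum of the Z-spectrum on a
#' cubic-spline interpolation over a 0.01-ppm grid and rigidly shifts the
#' spectrum so the minimum sits at 0 ppm, re-interpolating onto the
#' original axis. When the minimum falls on the boundary of the axis a
#' warning is issued and no shift is applied.
#'
#' @param z a [zspectrum()].
#' @return the corrected [zspectrum()], with the recovered shift (ppm) in
#'   attribute `"b0_shift_ppm"`.
#' @export
wassr_correct <- function(z) {
  stopifnot(inherits(z, "zspectrum"))
  shift <- find_water_shift(z)
  if (is.na(shift)) {
    warning("Z minimum at offset-axis boundary; no B0 correction applied")
    attr(z, "b0_shift_ppm") <- 0
    return(z)
  }
  zc <- shift_spectrum(z, -shift)
  attr(zc, "b0_shift_ppm") <- shift
  zc
}

# Sub-grid location of the water resonance (NA if on the axis boundary).
# The spline minimum alone is ill-conditioned when direct saturation
# flattens the bottom of the dip, so the coarse minimum is refined by
# maximum-symmetry matching: the center d minimizing the mismatch
# between the interpolated spectrum mirrored about d.
find_water_shift <- function(z, grid_ppm = 0.01, refine_ppm = 0.3) {
  rng <- range(z$offsets_ppm)
  n <- max(2L, ceiling(diff(rng) / grid_ppm) + 1L)
  sp <- stats::spline(z$offsets_ppm, z$z, n = n, method = "fmm")
  i <- which.min(sp$y)
  if (i == 1L || i == length(sp$y)) return(NA_real_)
  d0 <- sp$x[i]
  f <- stats::splinefun(z$offsets_ppm, z$z, method = "fmm")
  mismatch <- function(d) {
    xmax <- min(rng[2] - d, d - rng[1], 1)
    if (xmax <= grid_ppm) return(Inf)
    x <- seq(grid_ppm, xmax, by = grid_ppm)
    mean((f(d + x) - f(d - x))^2)
  }
  lo <- max(d0 - refine_ppm, rng[1]); hi <- min(d0 + refine_ppm, rng[2])
  stats::optimize(mismatch, c(lo, hi))$minimum
}

# rigid shift of the offset axis by `delta` ppm, resampled onto the
# original axis by cubic spline (natural extrapolation at the ends)
shift_spectrum <- function(z, delta) {
  f <- stats::splinefun(z$offsets_ppm + delta, z$z, method = "natural")
  zspectrum(f(z$offsets_ppm), z$offsets_ppm)
}

#' Magnetization transfer ratio asymmetry
#'
#' `MTR_asym(dw) = Z(-dw) - Z(+dw)`, evaluated on a symmetric offset grid
#' by cubic-spline interpolation and averaged over `range_ppm`, in
#' percent.
#'
#' @param z a [zspectrum()] normalized to the reference image.
#' @param range_ppm `c(low, high)` averaging window, e.g. `c(1.5, 2.5)`
#'   for creatine or `c(0.9, 1.9)` for the hydroxyl protons of
#'   glycosaminoglycans.
#' @param n_grid number of evaluation points in the window.
#' @return mean asymmetry in percent.
#' @export
mtr_asym <- function(z, range_ppm = c(1.5, 2.5), n_grid = 21L) {
  stopifnot(inherits(z, "zspectrum"), range_ppm[1] < range_ppm[2])
  stopifnot(range_ppm[2] <= max(z$offsets_ppm),
            -range_ppm[1] >= min(z$offsets_ppm))
  f <- stats::splinefun(z$offsets_ppm, z$z, method = "natural")
  dw <- seq(range_ppm[1], range_ppm[2], length.out = n_grid)
  mean(f(-dw) - f(dw)) * 100
}

#' Voxel-wise MTR asymmetry map with per-ROI statistics
#'
#' Applies [wassr_correct()] then [mtr_asym()] to every masked voxel and
#' summarises mean and standard deviation per region of interest.
#'
#' @param vol a [cest_volume()].
#' @param range_ppm asymmetry averaging window (ppm).
#' @param rois named list of logical ROI masks; defaults to a single ROI
#'   covering `vol$mask`.
#' @param wassr apply the B0 self-correction per voxel (default TRUE).
#' @return an object of class `mtr_asym_map`: list with percent-valued
#'   matrix `values` (`NA` outside the mask), `range_ppm` and data frame
#'   `roi_stats` (`roi`, `mean`, `sd`, `n`).
#' @export
mtr_asym_map <- function(vol, range_ppm = c(1.5, 2.5), rois = NULL,
                         wassr = TRUE) {
  stopifnot(inherits(vol, "cest_volume"))
  H <- dim(vol$data)[1]; W <- dim(vol$data)[2]
  values <- matrix(NA_real_, H, W)
  for (v in which(vol$mask)) {
    i <- (v - 1) %% H + 1; j <- (v - 1) %/% H + 1
    z <- voxel_spectrum(vol, i, j)
    if (wassr) z <- suppressWarnings(wassr_correct(z))
    values[i, j] <- mtr_asym(z, range_ppm)
  }
  if (is.null(rois)) rois <- list(mask = vol$mask)
  if (is.null(names(rois))) names(rois) <- paste0("roi", seq_along(rois))
  roi_stats <- do.call(rbind, lapply(names(rois), function(nm) {
    x <- values[rois[[nm]] & vol$mask]
    data.frame(roi = nm, mean = mean(x), sd = stats::sd(x), n = length(x))
  }))
  structure(list(values = values, range_ppm = range_ppm,
                 roi_stats = roi_stats),
            class = "mtr_asym_map")
}

#' @export
print.mtr_asym_map <- function(x, ...) {
  cat(sprintf("MTR_asym map over %.2f-%.2f ppm\n", x$range_ppm[1], x$range_ppm[2]))
  print(x$roi_stats, row.names = FALSE)
  invisible(x)
}
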