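#' CEST image stack
#'
#' Container for a 2D CEST acquisition: an `H x W x dyn` array of
#' normalized Z-values, the matching saturation-offset axis, the reference
#' (M0) image and a foreground mask.
#'
#' @param data numeric array `H x W x dyn` of Z-values (normalized to M0).
#' @param offsets_ppm numeric vector of length `dyn`.
#' @param m0 `H x W` reference image; defaults to all ones.
#' @param mask logical `H x W` foreground mask; when `NULL`, it is derived
#'   as `m0 > 0.1 * max(m0)`.
#' @param meta free-form provenance list (seed, sequence, pools, ...).
#' @return an object of class `cest_volume`.
#' @export
cest_volume <- function(data, offsets_ppm, m0 = NULL, mask = NULL,
                        meta = list()) {
  data <- as.array(data)
  stopifnot(length(dim(data)) == 3, dim(data)[3] == length(offsets_ppm))
  hw <- dim(data)[1:2]
  if (is.null(m0)) m0 <- matrix(1, hw[1], hw[2])
  stopifnot(all(dim(m0) == hw))
  if (is.null(mask)) mask <- m0 > 0.1 * max(m0)
  stopifnot(all(dim(mask) == hw), is.logical(mask))
  structure(list(data = data, offsets_ppm = as.numeric(offsets_ppm),
                 m0 = m0, mask = mask, dyn = length(offsets_ppm),
                 meta = meta),
            class = "cest_volume")
}

#' @export
print.cest_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("CEST volume: %d x %d x %d offsets [%.2f, %.2f] ppm, %d foreground voxels\n",
              d[1], d[2], d[3], min(x$offsets_ppm), max(x$offsets_ppm),
              sum(x$mask)))
  invisible(x)
}

#' A single-voxel Z-spectrum
#'
#' @param z numeric vector of normalized water signal per offset.
#' @param offsets_ppm matching offset axis (ppm).
#' @return an object of class `zspectrum`.
#' @export
zspectrum <- function(z, offsets_ppm) {
  stopifnot(length(z) == length(offsets_ppm))
  structure(list(z = as.numeric(z), offsets_ppm = as.numeric(offsets_ppm)),
            class = "zspectrum")
}

#' @export
print.zspectrum <- function(x, ...) {
  cat(sprintf("Z-spectrum: %d offsets [%.2f, %.2f] ppm, min Z %.3f at %.2f ppm\n",
              length(x$z), min(x$offsets_ppm), max(x$offsets_ppm),
              min(x$z), x$offsets_ppm[which.min(x$z)]))
  invisible(x)
}

#' Extract the Z-spectrum of one voxel
#'
#' @param vol a [cest_volume()].
#' @param i,j voxel row / column index.
#' @return a [zspectrum()].
#' @export
voxel_spectrum <- function(vol, i, j) {
  zspectrum(vol$data[i, j, ], vol$offsets_ppm)
}

# replace the data slab, keeping geometry/metadata
update_data <- function(vol, data, meta = vol$meta) {
  cest_volume(data, vol$offsets_ppm, m0 = vol$m0, mask = vol$mask, meta = meta)
}
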