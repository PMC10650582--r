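#' Minimal NIfTI-1 array IO
#'
#' Reads and writes uncompressed single-file NIfTI-1 (`.nii`) volumes
#' with float32 data, which is sufficient for the package's image
#' containers (no NIfTI package is required at run time). Orientation
#' metadata is not interpreted: arrays are stored in R's column-major
#' order as-is.
#'
#' @param x numeric array (2D or 3D) for `write_nifti`.
#' @param path file path ending in `.nii`.
#' @param pixdim voxel sizes, recycled to the array rank.
#' @return `read_nifti` returns the array; `write_nifti` the path,
#'   invisibly.
#' @export
write_nifti <- function(x, path, pixdim = 1) {
  x <- as.array(x)
  d <- dim(x)
  stopifnot(length(d) <= 7)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v, size) writeBin(as.integer(v), con, size = size, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                        # unused data_type..dim_info
  wi(c(length(d), d, rep(1L, 7 - length(d))), 2)  # dim[8]
  wf(c(0, 0, 0))                                # intent_p1..p3
  wi(0L, 2)                                     # intent_code
  wi(16L, 2)                                    # datatype = float32
  wi(32L, 2)                                    # bitpix
  wi(0L, 2)                                     # slice_start
  wf(c(0, rep(as.numeric(pixdim), length.out = 7)))  # pixdim[8]
  wf(352)                                       # vox_offset
  wf(c(1, 0))                                   # scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(2), con)              # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0))                                # cal_max, cal_min, slice_duration
  wf(0)                                         # toffset
  wi(c(0L, 0L), 4)                              # glmax, glmin
  writeBin(raw(104), con)                       # descrip, aux_file
  wi(c(0L, 0L), 2)                              # qform_code, sform_code
  wf(rep(0, 18))                                # quatern/qoffset/srow
  writeBin(raw(16), con)                        # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL)
  writeBin(raw(5), con)                         # magic NUL + extension flag
  writeBin(as.numeric(x), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_size <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (hdr_size != 348L) stop("not a NIfTI-1 file: ", path)
  invisible(readBin(con, "raw", 36))
  dim8 <- readBin(con, "integer", 8, size = 2, endian = "little")
  invisible(readBin(con, "raw", 14))
  datatype <- readBin(con, "integer", 1, size = 2, endian = "little")
  if (datatype != 16L) stop("only float32 NIfTI supported")
  invisible(readBin(con, "raw", 4))
  invisible(readBin(con, "numeric", 8, size = 4, endian = "little"))
  vox_offset <- readBin(con, "numeric", 1, size = 4, endian = "little")
  seek(con, vox_offset)
  d <- dim8[2:(1 + dim8[1])]
  x <- readBin(con, "numeric", prod(d), size = 4, endian = "little")
  array(x, dim = d)
}

#' Write / read a CEST volume as NIfTI + JSON sidecar
#'
#' The image stack goes to `<prefix>.nii`, the reference image to
#' `<prefix>_m0.nii`, and the offset axis, reference-offset, mask (run-
#' length free row-major logical) and free-form metadata to
#' `<prefix>.json`.
#'
#' @param vol a [cest_volume()].
#' @param prefix path prefix (no extension).
#' @return `read_cest_volume` returns the [cest_volume()];
#'   `write_cest_volume` the prefix, invisibly.
#' @export
write_cest_volume <- function(vol, prefix) {
  stopifnot(inherits(vol, "cest_volume"))
  write_nifti(vol$data, paste0(prefix, ".nii"))
  write_nifti(vol$m0, paste0(prefix, "_m0.nii"))
  sidecar <- list(offsets_ppm = vol$offsets_ppm,
                  ref_offset_ppm = vol$meta$seq$ref_offset_ppm %||% 300,
                  mask = as.integer(vol$mask),
                  meta = vol$meta)
  jsonlite::write_json(sidecar, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname write_cest_volume
#' @export
read_cest_volume <- function(prefix) {
  data <- read_nifti(paste0(prefix, ".nii"))
  m0 <- read_nifti(paste0(prefix, "_m0.nii"))
  sc <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  mask <- matrix(as.logical(sc$mask), dim(data)[1], dim(data)[2])
  cest_volume(data, sc$offsets_ppm, m0 = matrix(m0, dim(data)[1], dim(data)[2]),
              mask = mask, meta = as.list(sc$meta))
}

#' Write a label map as integer-valued NIfTI
#' @param label_map a `cest_label_map`.
#' @param path `.nii` path (labels stored as float32 integers).
#' @export
write_label_map <- function(label_map, path) {
  stopifnot(inherits(label_map, "cest_label_map"))
  write_nifti(label_map$labels, path)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  x <- read_nifti(path)
  as_label_map(matrix(as.integer(round(x)), nrow = dim(x)[1]))
}
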