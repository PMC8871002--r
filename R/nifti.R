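# Minimal NIfTI-1 reader/writer.
#
# Short-axis cardiac MR studies (e.g. the EMIDEC layout) ship one NIfTI
# volume of images and one of label masks per case.  No NIfTI package is
# available in this stack, so the subset of the format the pipeline needs is
# implemented here: single-file .nii / .nii.gz, 3D (or trailing singleton)
# grids, common datatypes, scl_slope/scl_inter scaling.  The affine is not
# interpreted; the third array axis is taken as the slice axis, which matches
# slice-last short-axis stacks.

NIFTI_DT <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `256` = list(what = "integer", size = 1L, signed = TRUE),   # int8
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

nifti_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`) into an array.
#' Intensity scaling (`scl_slope`, `scl_inter`) is applied when present.
#' Only the voxel grid and grid spacing are interpreted; orientation metadata
#' is ignored and the third axis is treated as the slice axis.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a list with `data` (numeric array), `pixdim` (grid spacing, mm)
#'   and `datatype` (NIfTI datatype code).
#' @seealso [write_nifti()], [volume_to_slices()]
#' @export
read_nifti <- function(path) {
  con <- nifti_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header: ", path, call. = FALSE)
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", 1L, 4L, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", 1L, 4L, endian = endian)
    if (sz != 348L) stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path, call. = FALSE)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("unsupported NIfTI magic '", magic, "' in ", path, call. = FALSE)
  dim8 <- readBin(hdr[41:56], "integer", 8L, 2L, endian = endian)
  ndim <- dim8[1L]
  if (ndim < 2L || ndim > 7L) stop("bad NIfTI ndim: ", ndim, call. = FALSE)
  dims <- dim8[2:(1L + ndim)]
  datatype <- readBin(hdr[71:72], "integer", 1L, 2L, endian = endian)
  pixdim <- readBin(hdr[77:108], "double", 8L, 4L, endian = endian)[2:(1L + ndim)]
  vox_offset <- readBin(hdr[109:112], "double", 1L, 4L, endian = endian)
  scl_slope <- readBin(hdr[113:116], "double", 1L, 4L, endian = endian)
  scl_inter <- readBin(hdr[117:120], "double", 1L, 4L, endian = endian)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype, call. = FALSE)
  skip <- as.integer(vox_offset) - 348L
  if (skip > 0L) readBin(con, "raw", skip)
  n <- prod(dims)
  vals <- readBin(con, dt$what, n, dt$size, signed = dt$signed, endian = endian)
  if (length(vals) != n) stop("truncated NIfTI data in ", path, call. = FALSE)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  data <- array(vals, dim = dims)
  list(data = data, pixdim = pixdim, datatype = datatype)
}

#' Write a NIfTI-1 volume
#'
#' Writes an array as a single-file NIfTI-1 image with an identity-like
#' orientation.  Integer arrays are stored as int16 (or uint8 when all values
#' fit in 0..255); doubles as float32.
#'
#' @param data numeric array (2D or 3D).
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param pixdim grid spacing per axis in mm.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, pixdim = rep(1, length(dim(data)))) {
  dims <- dim(data)
  if (is.null(dims) || length(dims) < 2L || length(dims) > 7L)
    stop("`data` must be a 2D..7D array", call. = FALSE)
  store_int <- is.integer(data) || all(data == round(data))
  if (store_int && all(data >= 0 & data <= 255)) {
    datatype <- 2L; bitpix <- 8L; size <- 1L; what <- "integer"
  } else if (store_int && all(abs(data) < 32768)) {
    datatype <- 4L; bitpix <- 16L; size <- 2L; what <- "integer"
  } else {
    datatype <- 16L; bitpix <- 32L; size <- 4L; what <- "double"
  }
  con <- nifti_con(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)
  wb(348L, 4L)                         # sizeof_hdr
  wraw(36L)                            # data_type, db_name, extents, session_error, regular, dim_info
  dim8 <- integer(8L); dim8[1L] <- length(dims); dim8[2:(1L + length(dims))] <- dims
  dim8[dim8 == 0L] <- 1L
  wb(dim8, 2L)                         # dim
  wraw(14L)                            # intent_p1..p3, intent_code
  wb(datatype, 2L); wb(bitpix, 2L); wb(0L, 2L)   # datatype, bitpix, slice_start
  pd <- numeric(8L); pd[2:(1L + length(pixdim))] <- pixdim
  wb(pd, 4L)                           # pixdim (qfac = 0)
  wb(352, 4L)                          # vox_offset
  wb(c(1, 0), 4L)                      # scl_slope, scl_inter
  wb(0L, 2L); wraw(1L); wraw(1L)       # slice_end, slice_code, xyzt_units
  wb(numeric(3L), 4L)                  # cal_max, cal_min, slice_duration
  wb(0, 4L)                            # toffset
  wb(c(0L, 0L), 4L)                    # glmax, glmin
  wraw(80L); wraw(24L)                 # descrip, aux_file
  wb(c(0L, 0L), 2L)                    # qform_code, sform_code
  wb(numeric(6L), 4L)                  # quatern_b..d, qoffset_x..z
  srow <- rbind(c(pd[2], 0, 0, 0), c(0, pd[3], 0, 0), c(0, 0, pd[4], 0))
  wb(as.numeric(t(srow)), 4L)          # srow_x/y/z
  wraw(16L)                            # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)    # magic (4 bytes)
  wraw(4L)                             # extension flag
  vals <- if (what == "integer") as.integer(data) else as.numeric(data)
  wb(vals, size)
  invisible(path)
}
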