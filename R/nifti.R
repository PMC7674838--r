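# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
# Only what co-registered scalar volumes need: 348-byte header, datatypes
# uint8/int16/int32/float32/float64, scl_slope/scl_inter rescaling, both
# endiannesses. Orientation handling is deliberately light: volumes written
# by this package carry an identity sform (RAS, 1 mm), and readers of
# external files get the raw voxel grid in file order.

NIFTI_HDR_SIZE <- 348L
NIFTI_VOX_OFFSET <- 352

.nifti_dtypes <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),
  `4`  = list(what = "integer", size = 2L, signed = TRUE),
  `8`  = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "numeric", size = 4L, signed = TRUE),
  `64` = list(what = "numeric", size = 8L, signed = TRUE)
)

.is_gz <- function(path) grepl("\\.gz$", path, ignore.case = TRUE)

.read_nifti_header <- function(con, endian) {
  hdr <- list()
  rd <- function(what, n, size, signed = TRUE)
    readBin(con, what = what, n = n, size = size, endian = endian,
            signed = signed)
  hdr$sizeof_hdr <- rd("integer", 1, 4)
  invisible(readBin(con, "raw", 36))           # data_type..dim_info (bytes 4-39)
  hdr$dim <- rd("integer", 8, 2)
  invisible(rd("numeric", 3, 4))               # intent_p1..p3
  invisible(rd("integer", 1, 2))               # intent_code
  hdr$datatype <- rd("integer", 1, 2)
  hdr$bitpix <- rd("integer", 1, 2)
  invisible(rd("integer", 1, 2))               # slice_start
  hdr$pixdim <- rd("numeric", 8, 4)
  hdr$vox_offset <- rd("numeric", 1, 4)
  hdr$scl_slope <- rd("numeric", 1, 4)
  hdr$scl_inter <- rd("numeric", 1, 4)
  invisible(rd("integer", 1, 2))               # slice_end
  invisible(rd("integer", 2, 1))               # slice_code, xyzt_units
  invisible(rd("numeric", 4, 4))               # cal_max..toffset
  invisible(rd("integer", 2, 4))               # glmax, glmin
  hdr$descrip <- rawToChar(readBin(con, "raw", 80))
  invisible(readBin(con, "raw", 24))           # aux_file
  hdr$qform_code <- rd("integer", 1, 2)
  hdr$sform_code <- rd("integer", 1, 2)
  invisible(rd("numeric", 6, 4))               # quaternion + qoffsets
  hdr$srow <- matrix(rd("numeric", 12, 4), nrow = 3, byrow = TRUE)
  invisible(readBin(con, "raw", 16))           # intent_name
  hdr$magic <- rawToChar(readBin(con, "raw", 4))
  hdr
}

#' Read a NIfTI-1 file
#'
#' Low-level reader returning the raw voxel array plus selected header
#' fields. Most users want [read_volume()], which validates the result and
#' wraps it in a `mri_volume`.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with elements `data` (numeric array), `dim`, `pixdim`,
#'   `descrip`, `datatype`.
#' @keywords internal
read_nifti <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  open_con <- function() if (.is_gz(path)) gzfile(path, "rb") else file(path, "rb")
  con <- open_con()
  on.exit(close(con), add = TRUE)
  first <- readBin(con, "integer", 1, 4, endian = "little")
  endian <- if (identical(first, NIFTI_HDR_SIZE)) "little" else "big"
  close(con)
  on.exit()                                    # reset: reopen below
  con <- open_con()
  on.exit(close(con), add = TRUE)
  hdr <- .read_nifti_header(con, endian)
  if (hdr$sizeof_hdr != NIFTI_HDR_SIZE)
    stop("malformed NIfTI-1 header (sizeof_hdr = ", hdr$sizeof_hdr, ")")
  if (!startsWith(hdr$magic, "n+1"))
    stop("not a single-file NIfTI-1 image (magic = ", hdr$magic, ")")
  ndim <- hdr$dim[1]
  if (ndim < 1L || ndim > 7L) stop("malformed NIfTI-1 header: dim[0] = ", ndim)
  dims <- hdr$dim[seq(2, 1 + ndim)]
  dt <- .nifti_dtypes[[as.character(hdr$datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", hdr$datatype)
  # skip from byte 348 to vox_offset
  skip <- round(hdr$vox_offset) - NIFTI_HDR_SIZE
  if (skip > 0) invisible(readBin(con, "raw", skip))
  n <- prod(dims)
  vals <- readBin(con, dt$what, n = n, size = dt$size, endian = endian,
                  signed = dt$signed)
  if (length(vals) < n) stop("truncated NIfTI data section")
  vals <- as.numeric(vals)
  if (is.finite(hdr$scl_slope) && hdr$scl_slope != 0 &&
      !(hdr$scl_slope == 1 && hdr$scl_inter == 0))
    vals <- vals * hdr$scl_slope + hdr$scl_inter
  list(data = array(vals, dim = dims), dim = dims,
       pixdim = hdr$pixdim[seq(2, 1 + ndim)],
       descrip = sub("\\x00.*$", "", hdr$descrip),
       datatype = hdr$datatype, sform_code = hdr$sform_code, srow = hdr$srow)
}

#' Write a 3D array as a NIfTI-1 file
#'
#' Writes float32 data with an identity sform (code 1), so that volumes in a
#' cohort written by this package are trivially co-registered in file space.
#'
#' @param data Numeric 3D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param descrip Up to 79 characters stored in the header `descrip` field
#'   (used by this package to carry the registration-space tag).
#' @keywords internal
write_nifti <- function(data, path, descrip = "") {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  con <- if (.is_gz(path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)
  wr_i <- function(x, size) writeBin(as.integer(x), con, size = size,
                                     endian = "little")
  wr_f <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  pad <- function(s, n) {
    r <- charToRaw(substr(s, 1, n - 1))
    c(r, raw(n - length(r)))
  }
  wr_i(NIFTI_HDR_SIZE, 4)                      # sizeof_hdr
  writeBin(raw(36), con)                       # data_type..dim_info
  wr_i(c(3L, dim(data), 1L, 1L, 1L, 1L), 2)    # dim[8]
  wr_f(c(0, 0, 0))                             # intent_p1..p3
  wr_i(0, 2)                                   # intent_code
  wr_i(16L, 2)                                 # datatype: float32
  wr_i(32L, 2)                                 # bitpix
  wr_i(0, 2)                                   # slice_start
  wr_f(c(0, 1, 1, 1, 0, 0, 0, 0))              # pixdim (qfac, 1 mm iso)
  wr_f(NIFTI_VOX_OFFSET)                       # vox_offset
  wr_f(1); wr_f(0)                             # scl_slope, scl_inter
  wr_i(0, 2)                                   # slice_end
  writeBin(as.raw(c(0, 10)), con)              # slice_code, xyzt_units (mm)
  wr_f(c(0, 0, 0, 0))                          # cal_max..toffset
  wr_i(c(0, 0), 4)                             # glmax, glmin
  writeBin(pad(descrip, 80), con)
  writeBin(raw(24), con)                       # aux_file
  wr_i(0, 2); wr_i(1, 2)                       # qform_code, sform_code
  wr_f(rep(0, 6))                              # quaternion, qoffsets
  wr_f(c(1, 0, 0, 0)); wr_f(c(0, 1, 0, 0)); wr_f(c(0, 0, 1, 0))
  writeBin(raw(16), con)                       # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)   # magic
  writeBin(raw(4), con)                        # extension flag (none)
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  invisible(path)
}
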