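# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O.
#
# The wider R stack available to this package has no NIfTI reader, so a
# small self-contained implementation of the NIfTI-1 format is provided,
# restricted to the subset this pipeline emits and consumes: single-file
# magic "n+1", 3D or 4D arrays, datatypes uint8/int16/int32/float32/float64,
# little- or big-endian headers, scl_slope/scl_inter honored on read.
# Orientation is stored as a diagonal sform built from the voxel spacing
# and carried through untouched; no resampling or reorientation is done.

NIFTI_DATATYPES <- list(
  uint8   = list(code = 2L,  bitpix = 8L,  what = "integer", size = 1L, signed = FALSE),
  int16   = list(code = 4L,  bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32   = list(code = 8L,  bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L, bitpix = 32L, what = "double",  size = 4L, signed = TRUE),
  float64 = list(code = 64L, bitpix = 64L, what = "double",  size = 8L, signed = TRUE)
)

nifti_connection <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3D/4D array as a NIfTI-1 file
#'
#' @param img numeric or logical array with 3 or 4 dimensions.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param voxel_spacing voxel edge lengths in mm, length 3.
#' @param datatype on-disk storage type: one of `"uint8"`, `"int16"`,
#'   `"int32"`, `"float32"`, `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(img, path, voxel_spacing = c(1, 1, 1),
                        datatype = "float32") {
  stopifnot(is.array(img), length(dim(img)) %in% c(3L, 4L))
  dt <- NIFTI_DATATYPES[[datatype]]
  if (is.null(dt)) stop("unsupported NIfTI datatype: ", datatype)
  dims <- dim(img)
  ndim <- length(dims)
  dim8 <- c(ndim, dims, rep(1L, 7L - ndim))
  pixdim8 <- c(1, voxel_spacing, rep(1, 4L))

  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wint <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wflt <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)

  wint(348L, 4L)                              # sizeof_hdr
  wraw(36L)                                   # data_type..dim_info
  wint(dim8, 2L)                              # dim[8]
  wflt(c(0, 0, 0)); wint(0L, 2L)              # intent_p1..3, intent_code
  wint(dt$code, 2L); wint(dt$bitpix, 2L)      # datatype, bitpix
  wint(0L, 2L)                                # slice_start
  wflt(pixdim8)                               # pixdim[8]
  wflt(352)                                   # vox_offset
  wflt(1); wflt(0)                            # scl_slope, scl_inter
  wint(0L, 2L); wraw(2L)                      # slice_end, slice_code, xyzt_units
  wflt(c(0, 0, 0, 0))                         # cal_max, cal_min, slice_duration, toffset
  wint(c(0L, 0L), 4L)                         # glmax, glmin
  desc <- charToRaw("skindwi")
  writeBin(c(desc, raw(80L - length(desc))), con)   # descrip[80]
  wraw(24L)                                   # aux_file
  wint(0L, 2L); wint(1L, 2L)                  # qform_code = 0, sform_code = 1
  wflt(rep(0, 6))                             # quatern_b..d, qoffset_x..z
  wflt(c(voxel_spacing[1], 0, 0, 0))          # srow_x
  wflt(c(0, voxel_spacing[2], 0, 0))          # srow_y
  wflt(c(0, 0, voxel_spacing[3], 0))          # srow_z
  wraw(16L)                                   # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con) # magic
  wraw(4L)                                    # extension flag

  vals <- as.vector(img)
  if (dt$what == "integer") {
    vals <- as.integer(round(vals))
    writeBin(vals, con, size = dt$size, endian = "little")
  } else {
    writeBin(as.double(vals), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 file
#'
#' Returns the voxel data with `scl_slope`/`scl_inter` applied, plus the
#' voxel spacing and a few header fields.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return list with elements `data` (array), `voxel_spacing` (length-3
#'   numeric, mm), `datatype` (name), and `dim` (integer vector).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header in ", path)

  rint <- function(off, size, n = 1L, endian) {
    readBin(hdr[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            endian = endian)
  }
  rflt <- function(off, n = 1L, endian) {
    readBin(hdr[(off + 1L):(off + 4L * n)], "double", n = n, size = 4L,
            endian = endian)
  }
  endian <- "little"
  if (rint(0L, 4L, endian = endian) != 348L) {
    endian <- "big"
    if (rint(0L, 4L, endian = endian) != 348L)
      stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("unrecognised NIfTI magic: ", path)
  if (magic == "ni1") stop("two-file NIfTI (.hdr/.img) is not supported")

  dim8 <- rint(40L, 2L, 8L, endian)
  ndim <- dim8[1]
  if (ndim < 3L || ndim > 4L) stop("only 3D/4D NIfTI supported, got ndim=", ndim)
  dims <- dim8[2:(1 + ndim)]
  dtcode <- rint(70L, 2L, endian = endian)
  dt_idx <- which(vapply(NIFTI_DATATYPES, function(d) d$code == dtcode, logical(1)))
  if (length(dt_idx) != 1L) stop("unsupported NIfTI datatype code: ", dtcode)
  dt <- NIFTI_DATATYPES[[dt_idx]]
  pixdim <- rflt(76L, 8L, endian)
  vox_offset <- rflt(108L, 1L, endian)
  scl_slope <- rflt(112L, 1L, endian)
  scl_inter <- rflt(116L, 1L, endian)

  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  nvox <- prod(dims)
  vals <- readBin(con, dt$what, n = nvox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) != nvox) stop("truncated NIfTI data in ", path)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(as.double(vals), dim = dims),
       voxel_spacing = abs(pixdim[2:4]),
       datatype = names(NIFTI_DATATYPES)[dt_idx],
       dim = as.integer(dims))
}
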