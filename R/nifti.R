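#' Minimal NIfTI-1 volume I/O
#'
#' Self-contained reader/writer for single-file NIfTI-1 (`.nii`, `.nii.gz`)
#' volumes, covering the subset of the format this package emits and consumes:
#' little-endian, 3D, datatypes uint8/int16/int32/float32/float64, with voxel
#' spacing carried in `pixdim`. Arrays use the package-wide spatial convention
#' `(z, y, x)`: the first (fastest-varying) array axis is the slice axis `z`
#' and the last is the patient left-right axis `x`.
#'
#' @param path file path; a `.gz` suffix selects gzip compression transparently.
#' @param data numeric 3D array to write.
#' @param spacing_mm positive numeric length-3 voxel spacing `(z, y, x)` in mm.
#' @param datatype one of `"float32"`, `"float64"`, `"uint8"`, `"int16"`,
#'   `"int32"`.
#' @return `read_nifti()` returns a numeric 3D array with attributes
#'   `spacing_mm`; `write_nifti()` returns `path` invisibly.
#' @name nifti_io
NULL

.nifti_dtypes <- list(
  uint8   = list(code = 2L,   bitpix = 8L,  what = "integer", size = 1L, signed = FALSE),
  int16   = list(code = 4L,   bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32   = list(code = 8L,   bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L,  bitpix = 32L, what = "double",  size = 4L, signed = TRUE),
  float64 = list(code = 64L,  bitpix = 64L, what = "double",  size = 8L, signed = TRUE)
)

.nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' @rdname nifti_io
#' @export
write_nifti <- function(data, path, spacing_mm = c(1, 1, 1), datatype = "float32") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be three positive finite values", call. = FALSE)
  dt <- .nifti_dtypes[[match.arg(datatype, names(.nifti_dtypes))]]
  dims <- dim(data)
  con <- .nifti_open(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)
  wi(348L, 4L)                      # sizeof_hdr
  wraw(36L)                         # data_type, db_name, extents, session_error, regular, dim_info
  wi(c(3L, dims, 1L, 1L, 1L, 1L), 2L)  # dim[8]
  wraw(14L)                         # intent_p1..3, intent_code
  wi(dt$code, 2L)                   # datatype
  wi(dt$bitpix, 2L)                 # bitpix
  wi(0L, 2L)                        # slice_start
  wf(c(1, spacing_mm, 0, 0, 0, 0)) # pixdim[8] (qfac = 1)
  wf(352)                           # vox_offset
  wf(1); wf(0)                      # scl_slope, scl_inter
  wi(0L, 2L); wraw(1L); wraw(1L)    # slice_end, slice_code, xyzt_units
  wf(0); wf(0); wf(0)               # cal_max, cal_min, slice_duration
  wf(0)                             # toffset
  wi(c(0L, 0L), 4L)                 # glmax, glmin
  wraw(80L); wraw(24L)              # descrip, aux_file
  wi(c(0L, 0L), 2L)                 # qform_code, sform_code
  wf(numeric(18))                   # quaternions + srow
  wraw(16L)                         # intent_name
  writeChar("n+1", con, nchars = 3L, eos = NULL); wraw(1L)  # magic
  wraw(4L)                          # extension flag
  vals <- as.vector(data)
  if (dt$what == "integer") {
    if (any(vals != round(vals))) stop("non-integer data for integer datatype", call. = FALSE)
    writeBin(as.integer(vals), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.double(vals), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_nifti <- function(path) {
  con <- .nifti_open(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 352L)
  if (length(hdr) < 348L) stop("truncated NIfTI header: ", path, call. = FALSE)
  ri <- function(off, size, n = 1L, signed = TRUE)
    readBin(hdr[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            endian = "little", signed = signed)
  rf <- function(off, n = 1L)
    readBin(hdr[(off + 1L):(off + 4L * n)], "double", n = n, size = 4L, endian = "little")
  if (ri(0L, 4L) != 348L) stop("not a little-endian NIfTI-1 file: ", path, call. = FALSE)
  dim8 <- ri(40L, 2L, 8L)
  ndim <- dim8[1L]
  if (ndim < 3L) stop("expected a 3D volume: ", path, call. = FALSE)
  dims <- dim8[2L:(1L + ndim)]
  if (ndim > 3L) {
    if (any(dims[4:length(dims)] > 1L))
      stop("multi-volume NIfTI files are unsupported (one file per series): ", path, call. = FALSE)
    dims <- dims[1:3]
  }
  dtcode <- ri(70L, 2L)
  dt <- Filter(function(d) d$code == dtcode, .nifti_dtypes)
  if (!length(dt)) stop("unsupported NIfTI datatype code ", dtcode, call. = FALSE)
  dt <- dt[[1L]]
  pixdim <- rf(76L, 8L)
  vox_offset <- rf(108L)
  scl_slope <- rf(112L); scl_inter <- rf(116L)
  n <- prod(dims)
  skip <- as.integer(vox_offset) - 352L
  if (skip > 0L) readBin(con, "raw", n = skip)
  vals <- readBin(con, dt$what, n = n, size = dt$size, endian = "little",
                  signed = if (dt$what == "integer") dt$signed else TRUE)
  if (length(vals) != n) stop("truncated NIfTI data: ", path, call. = FALSE)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  out <- array(vals, dim = dims)
  attr(out, "spacing_mm") <- pixdim[2:4]
  out
}
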