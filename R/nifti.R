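# Minimal single-file NIfTI-1 (.nii) I/O.
#
# No NIfTI package is available in the deployment environment, so the package
# carries the small subset of the format it needs: uncompressed single-file
# volumes, float32 data, identity orientation, TR stored in pixdim[4] (the
# 4th-dimension spacing, seconds via xyzt_units). Enough for round-tripping
# the phantoms and quality maps; not a general-purpose NIfTI implementation.

NIFTI_HDR_SIZE <- 348L
NIFTI_VOX_OFFSET <- 352
DT_FLOAT32 <- 16L

#' Write a 3D/4D array as a NIfTI-1 volume
#'
#' Data are stored as float32, little-endian, single-file `.nii`. For 4D
#' volumes the repetition time is recorded as the 4th-dimension spacing with
#' time units of seconds.
#'
#' @param data a 3D or 4D numeric array; `NA` values are written as NaN.
#' @param path output path (`.nii`).
#' @param pixdim spatial voxel size, length 3 (mm).
#' @param tr_seconds repetition time for 4D volumes (seconds).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, pixdim = c(1, 1, 1), tr_seconds = 0) {
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L))
    qc_abort("only 3D/4D volumes are supported", "dscqc_not_4d")
  dims <- rep(1L, 8L)
  dims[1L] <- nd
  dims[2L:(1L + nd)] <- dim(data)
  pd <- rep(0, 8L)
  pd[1L] <- 1                       # qfac
  pd[2L:4L] <- pixdim
  if (nd == 4L) pd[5L] <- tr_seconds

  con <- file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)
  w_char <- function(s, n) {
    b <- charToRaw(s)
    writeBin(c(b, raw(n - length(b))), con)
  }

  w_i32(NIFTI_HDR_SIZE)             # sizeof_hdr
  w_raw(36L)                        # data_type[10] + db_name[18] + extents + session_error + regular + dim_info
  w_i16(dims)                       # dim[8]
  w_f32(c(0, 0, 0))                 # intent_p1..p3
  w_i16(0L)                         # intent_code
  w_i16(DT_FLOAT32)                 # datatype
  w_i16(32L)                        # bitpix
  w_i16(0L)                         # slice_start
  w_f32(pd)                         # pixdim[8]
  w_f32(NIFTI_VOX_OFFSET)           # vox_offset
  w_f32(1)                          # scl_slope
  w_f32(0)                          # scl_inter
  w_i16(0L)                         # slice_end
  w_raw(2L)                         # slice_code + xyzt_units (written below)
  seek(con, 123, rw = "write")      # xyzt_units byte
  writeBin(as.raw(bitwOr(2L, 8L)), con)  # NIFTI_UNITS_MM | NIFTI_UNITS_SEC
  w_f32(c(0, 0))                    # cal_max, cal_min
  w_f32(c(0, 0))                    # slice_duration, toffset
  w_i32(c(0L, 0L))                  # glmax, glmin
  w_char("dscqc synthetic/QC volume", 80L)  # descrip
  w_raw(24L)                        # aux_file
  w_i16(0L)                         # qform_code
  w_i16(1L)                         # sform_code: scaled identity
  w_f32(c(0, 0, 0, 0, 0, 0))        # quatern b,c,d + qoffset x,y,z
  w_f32(c(pixdim[1L], 0, 0, 0))     # srow_x
  w_f32(c(0, pixdim[2L], 0, 0))     # srow_y
  w_f32(c(0, 0, pixdim[3L], 0))     # srow_z
  w_char("", 16L)                   # intent_name
  w_char("n+1", 4L)                 # magic (zero-padded)
  w_raw(4L)                         # extension flag = 0
  vals <- as.numeric(data)
  vals[is.na(vals)] <- NaN
  w_f32(vals)
  invisible(path)
}

#' Read a NIfTI-1 volume written by this package (or any float/int
#' single-file `.nii` with unscaled data)
#'
#' @param path path to a `.nii` file.
#' @return a list with `data` (array), `dim`, `pixdim` (spatial),
#'   `tr_seconds` (4th-dimension spacing; 0 for 3D volumes).
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  r_i32 <- function(n) readBin(con, "integer", n, size = 4L, endian = "little")
  r_i16 <- function(n) readBin(con, "integer", n, size = 2L, endian = "little")
  r_f32 <- function(n) readBin(con, "double", n, size = 4L, endian = "little")

  if (r_i32(1L) != NIFTI_HDR_SIZE)
    qc_abort("not a little-endian NIfTI-1 file", "dscqc_bad_nifti")
  seek(con, 40)
  dims <- r_i16(8L)
  nd <- dims[1L]
  if (!nd %in% c(2L, 3L, 4L))
    qc_abort("unsupported dimensionality", "dscqc_bad_nifti")
  seek(con, 70)
  datatype <- r_i16(1L)
  seek(con, 76)
  pd <- r_f32(8L)
  vox_offset <- r_f32(1L)
  scl_slope <- r_f32(1L)
  scl_inter <- r_f32(1L)

  n_vox <- prod(dims[2L:(1L + nd)])
  seek(con, vox_offset)
  vals <- switch(as.character(datatype),
    "16" = r_f32(n_vox),
    "64" = readBin(con, "double", n_vox, size = 8L, endian = "little"),
    "4" = as.numeric(r_i16(n_vox)),
    "8" = as.numeric(r_i32(n_vox)),
    "2" = as.numeric(readBin(con, "integer", n_vox, size = 1L, signed = FALSE)),
    qc_abort(sprintf("unsupported NIfTI datatype %d", datatype), "dscqc_bad_nifti")
  )
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(vals, dim = dims[2L:(1L + nd)]),
       dim = dims[2L:(1L + nd)],
       pixdim = pd[2L:4L],
       tr_seconds = if (nd == 4L) pd[5L] else 0)
}
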