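# Minimal NIfTI-1 reader/writer for axis-aligned 3D volumes.
#
# Only single-file .nii / .nii.gz with a 348-byte NIfTI-1 header is
# supported. Geometry is restricted to axis-aligned spacing + origin
# (sform with a diagonal rotation part, or pixdim + qoffset); oblique
# acquisitions and 4D data are rejected. Images are written as float32,
# label masks as unsigned integers.

NIFTI_DT <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "numeric", size = 4L, signed = TRUE),
  `64`  = list(what = "numeric", size = 8L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE))

openVolumeConn <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a 3D NIfTI volume
#'
#' @param path path to a `.nii` or `.nii.gz` file with 3D data.
#' @param label if TRUE return a [LabelMask-class] (data must be
#'   non-negative integers), else a [Volume-class].
#' @return A [Volume-class] or [LabelMask-class] carrying the file's voxel
#'   spacing and origin; intensities are unmodified (scl_slope/inter are
#'   applied when present).
#' @export
readVolume <- function(path, label = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- openVolumeConn(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, raw(), n = 348L)
  if (length(hdr) < 348L) stop("not a NIfTI-1 file (truncated header): ", path)
  endian <- "little"
  szh <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
  if (szh != 348L) {
    endian <- "big"
    szh <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
    if (szh != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  rd <- function(off, what, n, size) {
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = TRUE)
  }
  dims <- rd(40, "integer", 8, 2L)
  datatype <- rd(70, "integer", 1, 2L)
  pixdim <- rd(76, "numeric", 8, 4L)
  vox_offset <- rd(108, "numeric", 1, 4L)
  scl_slope <- rd(112, "numeric", 1, 4L)
  scl_inter <- rd(116, "numeric", 1, 4L)
  qform_code <- rd(252, "integer", 1, 2L)
  sform_code <- rd(254, "integer", 1, 2L)
  qoffset <- rd(268, "numeric", 3, 4L)
  srow <- rbind(rd(280, "numeric", 4, 4L), rd(296, "numeric", 4, 4L),
                rd(312, "numeric", 4, 4L))

  nd <- dims[1]
  if (nd != 3L) stop("expected 3D volume, got ", nd, "D: ", path)
  shape <- dims[2:4]
  if (any(shape < 1L)) stop("invalid dimensions in ", path)

  if (sform_code > 0L) {
    rot <- srow[, 1:3]
    if (any(abs(rot - diag(diag(rot))) > 1e-5 * max(abs(rot))))
      stop("oblique (non-axis-aligned) volumes are not supported: ", path)
    sp <- abs(diag(rot))
    orig <- srow[, 4]
  } else {
    sp <- abs(pixdim[2:4])
    orig <- if (qform_code > 0L) qoffset else c(0, 0, 0)
  }
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("non-positive voxel spacing in ", path)

  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype ", datatype, ": ", path)
  skip <- max(0, round(vox_offset) - 348L)
  if (skip > 0) readBin(con, raw(), n = skip)
  n <- prod(shape)
  x <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
               endian = endian)
  if (length(x) < n) stop("truncated data section in ", path)
  x <- as.numeric(x)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    x <- x * scl_slope + scl_inter
  arr <- array(x, dim = shape)
  if (label) LabelMask(arr, sp, orig) else Volume(arr, sp, orig)
}

#' Write a volume or label mask as NIfTI-1
#'
#' Images are stored as float32; label masks as uint8 (uint16 when labels
#' exceed 255). Spacing goes to `pixdim` and to a diagonal sform; the
#' origin to the sform translation.
#'
#' @param v a [Volume-class] or [LabelMask-class].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(v, path) {
  validObject(v)
  shape <- dim(v@data)
  isLab <- is(v, "LabelMask")
  if (isLab) {
    if (max(v@data) > 65535) stop("label values exceed uint16 range")
    datatype <- if (max(v@data) > 255) 512L else 2L
  } else datatype <- 16L
  dt <- NIFTI_DT[[as.character(datatype)]]
  bitpix <- dt$size * 8L

  con <- openVolumeConn(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")
  w(348L, 4L)                                   # sizeof_hdr
  w(raw(36), 1L)                                # data_type..dim_info
  w(as.integer(c(3L, shape, 1L, 1L, 1L, 1L)), 2L)  # dim[8]
  w(numeric(3), 4L)                             # intent_p1..p3
  w(0L, 2L)                                     # intent_code
  w(datatype, 2L)
  w(bitpix, 2L)
  w(0L, 2L)                                     # slice_start
  w(c(1, v@spacing, 0, 0, 0, 0), 4L)            # pixdim[8] (qfac = 1)
  w(352, 4L)                                    # vox_offset
  w(c(1, 0), 4L)                                # scl_slope, scl_inter
  w(0L, 2L); w(raw(2), 1L)                      # slice_end, slice_code/xyzt
  w(numeric(4), 4L)                             # cal_max..slice_duration... (4 floats: cal_max cal_min slice_duration toffset)
  w(c(0L, 0L), 4L)                              # glmax, glmin
  w(raw(104), 1L)                               # descrip + aux_file
  w(c(0L, 1L), 2L)                              # qform_code, sform_code
  w(numeric(3), 4L)                             # quatern_b,c,d
  w(v@origin, 4L)                               # qoffset (informational)
  w(c(v@spacing[1], 0, 0, v@origin[1]), 4L)     # srow_x
  w(c(0, v@spacing[2], 0, v@origin[2]), 4L)     # srow_y
  w(c(0, 0, v@spacing[3], v@origin[3]), 4L)     # srow_z
  w(raw(16), 1L)                                # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL); w(raw(1), 1L)  # magic
  w(raw(4), 1L)                                 # extension flag
  if (dt$what == "integer") {
    w(as.integer(v@data), dt$size)
  } else {
    w(as.numeric(v@data), 4L)
  }
  invisible(path)
}
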