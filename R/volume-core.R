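# Constructors, accessors and geometric operations on volumes.

#' Create a Volume
#'
#' @param data 3D numeric array.
#' @param spacing voxel spacing in mm (length 3, recycled from length 1).
#' @param origin physical coordinate of voxel (0,0,0) in mm.
#' @return A [Volume-class] object.
#' @examples
#' v <- Volume(array(0, c(8, 8, 8)), spacing = c(1, 1, 3))
#' spacing(v)
#' @export
Volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("Volume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Create a LabelMask
#'
#' @param data 3D array of non-negative integer labels (0 = background).
#' @inheritParams Volume
#' @return A [LabelMask-class] object.
#' @export
LabelMask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  storage.mode(data) <- "double"
  new("LabelMask", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Create a BoundingBox
#'
#' Voxel indices are 0-based; the box is half-open: `lo` inclusive, `hi`
#' exclusive.
#'
#' @param lo,hi integer corners (length 3).
#' @return A [BoundingBox-class] object.
#' @export
BoundingBox <- function(lo, hi) {
  new("BoundingBox", lo = as.integer(lo), hi = as.integer(hi))
}

#' @rdname NormalizationSpec-class
#' @param windowLevel,windowWidth CT window centre / width.
#' @export
ctWindowSpec <- function(windowLevel = 40, windowWidth = 400) {
  new("NormalizationSpec", mode = "ct_window", windowLevel = windowLevel,
      windowWidth = windowWidth)
}

#' @rdname NormalizationSpec-class
#' @param lowerPct,upperPct percentile band for the MRI mode.
#' @export
mriPercentileSpec <- function(lowerPct = 0.5, upperPct = 99.5) {
  new("NormalizationSpec", mode = "mri_percentile", lowerPct = lowerPct,
      upperPct = upperPct)
}

# ---- accessors -------------------------------------------------------------

#' @describeIn Volume-class voxel data as a 3D array
#' @param v,object a Volume or LabelMask
#' @export
voxelData <- function(v) v@data

#' @describeIn Volume-class voxel spacing (mm)
#' @export
spacing <- function(v) v@spacing

#' @describeIn Volume-class physical coordinate of voxel (0,0,0)
#' @export
origin <- function(v) v@origin

#' @describeIn Volume-class grid shape (voxels per axis)
#' @export
gridShape <- function(v) dim(v@data)

setMethod("dim", "Volume", function(x) dim(x@data))

#' @describeIn BoundingBox-class inclusive lower corner (0-based)
#' @param box a BoundingBox
#' @export
boxLo <- function(box) box@lo

#' @describeIn BoundingBox-class exclusive upper corner
#' @export
boxHi <- function(box) box@hi

#' @describeIn BoundingBox-class box shape `hi - lo`
#' @export
boxShape <- function(box) box@hi - box@lo

setMethod("show", "Volume", function(object) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin (%s)\n",
              class(object), paste(dim(object@data), collapse = "x"),
              paste(format(object@spacing, trim = TRUE), collapse = "x"),
              paste(format(object@origin, trim = TRUE), collapse = ", ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "LabelMask", function(object) {
  labs <- sort(unique(as.vector(object@data)))
  cat(sprintf("<LabelMask> %s voxels, spacing %s mm, labels {%s}\n",
              paste(dim(object@data), collapse = "x"),
              paste(format(object@spacing, trim = TRUE), collapse = "x"),
              paste(labs, collapse = ", ")))
})

setMethod("show", "BoundingBox", function(object) {
  cat(sprintf("<BoundingBox> [%s) - [%s), shape %s\n",
              paste(object@lo, collapse = ","), paste(object@hi, collapse = ","),
              paste(object@hi - object@lo, collapse = "x")))
})

# rebuild an object of the same class with new data/geometry
sameType <- function(v, data, spacing = v@spacing, origin = v@origin) {
  if (is(v, "LabelMask")) LabelMask(data, spacing, origin)
  else Volume(data, spacing, origin)
}

# ---- resampling ------------------------------------------------------------

#' Resample a volume to a new voxel spacing
#'
#' The output grid has shape `round(shape * spacing / targetSpacing)` with a
#' floor of 1 voxel per axis, the same origin, and the target spacing.
#' Output voxel (i,j,k) samples the input at continuous index
#' `i * target/input` per axis: nearest-neighbour rounds the index, linear
#' interpolates trilinearly. Label masks must use nearest-neighbour (linear
#' interpolation would fabricate non-existent classes).
#'
#' @param v a [Volume-class] or [LabelMask-class].
#' @param targetSpacing new spacing in mm (length 3 or 1).
#' @param method `"nearest"` or `"linear"`.
#' @return An object of the same class as `v` on the resampled grid.
#' @examples
#' v <- Volume(array(rnorm(8^3), c(8, 8, 8)), spacing = 1)
#' dim(resampleVolume(v, 5))  # c(2, 2, 2)
#' @export
resampleVolume <- function(v, targetSpacing, method = c("nearest", "linear")) {
  method <- match.arg(method)
  if (length(targetSpacing) == 1L) targetSpacing <- rep(targetSpacing, 3L)
  if (any(!is.finite(targetSpacing)) || any(targetSpacing <= 0))
    stop("targetSpacing must be strictly positive")
  if (is(v, "LabelMask") && method != "nearest")
    stop("labels are never linearly interpolated; use method = 'nearest'")
  inShape <- dim(v@data)
  if (all(targetSpacing == v@spacing)) return(v)
  outShape <- pmax(1L, as.integer(round(inShape * v@spacing / targetSpacing)))
  ratio <- targetSpacing / v@spacing
  if (method == "nearest") {
    idx <- lapply(1:3, function(a) {
      i <- round((seq_len(outShape[a]) - 1) * ratio[a]) + 1
      pmin(pmax(i, 1L), inShape[a])
    })
    out <- v@data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  } else {
    cont <- lapply(1:3, function(a) (seq_len(outShape[a]) - 1) * ratio[a])
    out <- trilinearGrid(v@data, cont[[1]], cont[[2]], cont[[3]])
  }
  dim(out) <- outShape
  sameType(v, out, spacing = targetSpacing)
}

# trilinear interpolation of a 3D array on the tensor grid cx x cy x cz of
# continuous 0-based indices (clamped to the grid)
trilinearGrid <- function(a, cx, cy, cz) {
  d <- dim(a)
  clamp <- function(x, n) pmin(pmax(x, 0), n - 1)
  cx <- clamp(cx, d[1]); cy <- clamp(cy, d[2]); cz <- clamp(cz, d[3])
  x0 <- pmin(floor(cx), d[1] - 1); fx <- cx - x0
  y0 <- pmin(floor(cy), d[2] - 1); fy <- cy - y0
  z0 <- pmin(floor(cz), d[3] - 1); fz <- cz - z0
  x1 <- pmin(x0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1)
  z1 <- pmin(z0 + 1, d[3] - 1)
  nx <- length(cx); ny <- length(cy); nz <- length(cz)
  FX <- array(fx, c(nx, ny, nz))
  FY <- array(rep(fy, each = nx), c(nx, ny, nz))
  FZ <- array(rep(fz, each = nx * ny), c(nx, ny, nz))
  g <- function(ix, iy, iz)
    array(a[cbind(rep(ix + 1, times = ny * nz),
                  rep(rep(iy + 1, each = nx), times = nz),
                  rep(iz + 1, each = nx * ny))], c(nx, ny, nz))
  g(x0, y0, z0) * (1 - FX) * (1 - FY) * (1 - FZ) +
    g(x1, y0, z0) * FX * (1 - FY) * (1 - FZ) +
    g(x0, y1, z0) * (1 - FX) * FY * (1 - FZ) +
    g(x1, y1, z0) * FX * FY * (1 - FZ) +
    g(x0, y0, z1) * (1 - FX) * (1 - FY) * FZ +
    g(x1, y0, z1) * FX * (1 - FY) * FZ +
    g(x0, y1, z1) * (1 - FX) * FY * FZ +
    g(x1, y1, z1) * FX * FY * FZ
}

# ---- intensity normalization ----------------------------------------------

#' Normalize intensities to [-1, 1]
#'
#' CT mode subtracts the window level and divides by half the window width;
#' MRI mode computes mean and SD over the `[lowerPct, upperPct]` percentile
#' band (values clipped to the band first) and z-scores with them. Both
#' modes clip the result to `[-1, 1]`; the mapping is monotone
#' non-decreasing in the input intensity.
#'
#' @param v a [Volume-class].
#' @param spec a [NormalizationSpec-class]; default CT window level 40 /
#'   width 400 (a generic soft-tissue window).
#' @return A normalized [Volume-class] with values in `[-1, 1]`.
#' @examples
#' v <- Volume(array(c(40, 240, 5000, -1000), c(4, 1, 1)))
#' voxelData(normalizeIntensity(v))[, 1, 1]  # 0, 1, 1, -1
#' @export
normalizeIntensity <- function(v, spec = ctWindowSpec()) {
  validObject(spec)
  x <- v@data
  if (spec@mode == "ct_window") {
    out <- (x - spec@windowLevel) / (spec@windowWidth / 2)
  } else {
    if (length(unique(as.vector(x))) < 2L)
      stop("MRI normalization needs at least 2 distinct intensities")
    band <- quantile(x, c(spec@lowerPct, spec@upperPct) / 100, names = FALSE)
    xc <- pmin(pmax(x, band[1]), band[2])
    s <- sd(xc)
    if (s == 0) stop("degenerate MRI intensity spread (zero SD in band)")
    out <- (xc - mean(xc)) / s
  }
  Volume(array(pmin(pmax(out, -1), 1), dim(x)), v@spacing, v@origin)
}

# ---- bounding boxes, crop, paste ------------------------------------------

#' Tight bounding box of a label, with physical margin
#'
#' Returns the tightest axis-aligned half-open box containing all voxels
#' equal to `label`, expanded by `ceiling(marginMm / spacing)` voxels per
#' side and clamped to the grid.
#'
#' @param m a [LabelMask-class].
#' @param label positive integer structure label.
#' @param marginMm non-negative margin in mm (length 3 or 1).
#' @return A [BoundingBox-class].
#' @export
boundingBoxOf <- function(m, label = 1L, marginMm = c(0, 0, 0)) {
  if (length(marginMm) == 1L) marginMm <- rep(marginMm, 3L)
  stopifnot(all(marginMm >= 0))
  hit <- which(m@data == label, arr.ind = TRUE)
  if (nrow(hit) == 0L)
    stop(sprintf("empty structure: label %s absent from mask", label))
  lo <- apply(hit, 2, min) - 1L  # to 0-based
  hi <- apply(hit, 2, max)       # exclusive = max 0-based + 1
  mv <- as.integer(ceiling(marginMm / m@spacing))
  shape <- dim(m@data)
  BoundingBox(pmax(lo - mv, 0L), pmin(hi + mv, shape))
}

#' Crop a volume to a bounding box
#'
#' The output has shape `hi - lo` and its origin is shifted by
#' `lo * spacing` so physical coordinates are preserved. The box must
#' intersect the grid; it is clamped to the grid before cropping.
#'
#' @param v a [Volume-class] or [LabelMask-class].
#' @param box a [BoundingBox-class] in `v`'s voxel indices.
#' @return The cropped object, same class as `v`.
#' @export
cropVolume <- function(v, box) {
  shape <- dim(v@data)
  lo <- pmax(box@lo, 0L); hi <- pmin(box@hi, shape)
  if (any(hi <= lo)) stop("bounding box does not intersect the grid")
  out <- v@data[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2], (lo[3] + 1):hi[3],
                drop = FALSE]
  sameType(v, out, origin = v@origin + lo * v@spacing)
}

#' Paste a cropped volume back onto a canvas
#'
#' Inverse of [cropVolume()]: writes `patch`'s voxels into `canvas` at
#' offset `lo` (0-based), clipping to the canvas.
#'
#' @param canvas destination [Volume-class] or [LabelMask-class].
#' @param patch the block to insert.
#' @param lo 0-based offset of the patch within the canvas.
#' @return `canvas` with the block overwritten.
#' @export
pasteVolume <- function(canvas, patch, lo) {
  shape <- dim(canvas@data)
  p <- dim(patch@data)
  lo <- as.integer(lo)
  hi <- pmin(lo + p, shape)
  lo2 <- pmax(lo, 0L)
  if (any(hi <= lo2)) return(canvas)
  src_lo <- lo2 - lo
  d <- canvas@data
  d[(lo2[1] + 1):hi[1], (lo2[2] + 1):hi[2], (lo2[3] + 1):hi[3]] <-
    patch@data[(src_lo[1] + 1):(hi[1] - lo[1]),
               (src_lo[2] + 1):(hi[2] - lo[2]),
               (src_lo[3] + 1):(hi[3] - lo[3])]
  sameType(canvas, d)
}
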