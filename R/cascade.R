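# Two-stage inference: coarse localization at low resolution, bounding-box
# crop, fine segmentation at high resolution with optional attention
# channels, sliding-window patch prediction and connected-component
# post-processing.

#' Construct a CascadeConfig
#'
#' @param coarseSpacing,fineSpacing,bboxMarginMm,windowOverlap,keepLargestCC,minCCVoxels,useOarMap,useBoundaryMap,strictCoarse
#'   see [CascadeConfig-class] for the defaults (5 mm / 1 mm, 10 mm
#'   margin, no overlap, keep largest component).
#' @export
CascadeConfig <- function(coarseSpacing = c(5, 5, 5), fineSpacing = c(1, 1, 1),
                          bboxMarginMm = c(10, 10, 10), windowOverlap = 0,
                          keepLargestCC = TRUE, minCCVoxels = 27L,
                          useOarMap = FALSE, useBoundaryMap = FALSE,
                          strictCoarse = FALSE) {
  if (length(coarseSpacing) == 1L) coarseSpacing <- rep(coarseSpacing, 3L)
  if (length(fineSpacing) == 1L) fineSpacing <- rep(fineSpacing, 3L)
  if (length(bboxMarginMm) == 1L) bboxMarginMm <- rep(bboxMarginMm, 3L)
  new("CascadeConfig", coarseSpacing = as.numeric(coarseSpacing),
      fineSpacing = as.numeric(fineSpacing),
      bboxMarginMm = as.numeric(bboxMarginMm),
      windowOverlap = windowOverlap, keepLargestCC = keepLargestCC,
      minCCVoxels = as.integer(minCCVoxels), useOarMap = useOarMap,
      useBoundaryMap = useBoundaryMap, strictCoarse = strictCoarse)
}

# window start offsets (0-based) covering [0, n) with patch p and overlap f
windowStarts <- function(n, p, f) {
  if (p >= n) return(0L)
  s <- max(1L, as.integer(round(p * (1 - f))))
  starts <- seq.int(0L, n - p, by = s)
  if (starts[length(starts)] != n - p) starts <- c(starts, n - p)
  unique(starts)
}

#' Sliding-window prediction of class probabilities
#'
#' Tiles the (normalized, optionally multi-channel) input with overlapping
#' patches, averages the per-voxel class probabilities over all covering
#' windows, and crops back to the input shape. Inputs smaller than one
#' patch are zero-padded (image channel at -1, attention channels at 0)
#' and cropped back.
#'
#' @param x input array (X, Y, Z) or (X, Y, Z, C) of normalized
#'   intensities (+ attention channels).
#' @param model a `vbnet_model` with matching `inChannels`.
#' @param patchSize patch shape (length 3 or 1).
#' @param windowOverlap overlap fraction in `[0, 1)`.
#' @return Array (X, Y, Z, outClasses) of probabilities summing to 1 per
#'   voxel; every voxel is covered by at least one window.
#' @export
slidingWindowPredict <- function(x, model, patchSize, windowOverlap = 0) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (length(patchSize) == 1L) patchSize <- rep(patchSize, 3L)
  d <- dim(x)
  if (d[4] != model$spec@inChannels)
    stop(sprintf("model expects %d channels, input has %d",
                 model$spec@inChannels, d[4]))
  padded <- pmax(d[1:3], patchSize)
  if (any(padded != d[1:3])) {
    xp <- array(0, c(padded, d[4]))
    xp[, , , 1] <- -1
    xp[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), ] <- x
    x <- xp
  }
  nC <- model$spec@outClasses
  acc <- array(0, c(padded, nC))
  cnt <- array(0, padded)
  sx <- windowStarts(padded[1], patchSize[1], windowOverlap)
  sy <- windowStarts(padded[2], patchSize[2], windowOverlap)
  sz <- windowStarts(padded[3], patchSize[3], windowOverlap)
  for (ox in sx) for (oy in sy) for (oz in sz) {
    ix <- (ox + 1):(ox + patchSize[1])
    iy <- (oy + 1):(oy + patchSize[2])
    iz <- (oz + 1):(oz + patchSize[3])
    probs <- predictProbs(model, x[ix, iy, iz, , drop = FALSE])
    acc[ix, iy, iz, ] <- acc[ix, iy, iz, , drop = FALSE] + probs
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
  }
  acc <- acc / as.vector(cnt)
  acc[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), , drop = FALSE]
}

argmaxClasses <- function(probs) {
  d <- dim(probs)
  m <- matrix(probs, prod(d[1:3]))
  best <- max.col(m, ties.method = "first") - 1L
  array(best, d[1:3])
}

#' Coarse-stage localization of a structure
#'
#' Resamples the raw image to the coarse spacing (nearest neighbour),
#' normalizes, predicts with the coarse model by sliding window, takes the
#' bounding box of the requested label in the argmax segmentation, maps
#' the box corners back to raw voxel coordinates via the spacing ratio,
#' expands by `bboxMarginMm` and clamps to the grid. If the label is
#' absent from the coarse prediction, either an error is raised
#' (`strictCoarse`) or the whole-image box is returned with a warning.
#'
#' @param image raw (unnormalized) [Volume-class].
#' @param model trained coarse `vbnet_model`.
#' @param cfg a [CascadeConfig-class].
#' @param label structure label to localize.
#' @param patchSize coarse patch size.
#' @param normSpec normalization; defaults to the model's training
#'   metadata when present.
#' @return A [BoundingBox-class] in raw-image voxel indices.
#' @export
coarseLocalize <- function(image, model, cfg = CascadeConfig(), label = 1L,
                           patchSize = c(96L, 96L, 96L), normSpec = NULL) {
  normSpec <- normSpec %||% normSpecFromMeta(model$meta$normalization)
  lowres <- resampleVolume(image, cfg@coarseSpacing, "nearest")
  xin <- normalizeIntensity(lowres, normSpec)
  probs <- slidingWindowPredict(voxelData(xin), model, patchSize,
                                cfg@windowOverlap)
  seg <- argmaxClasses(probs)
  if (!any(seg == label)) {
    if (cfg@strictCoarse)
      stop("coarse detection failure: label ", label, " not found")
    warning("coarse detection failure: falling back to whole-image box")
    return(BoundingBox(c(0L, 0L, 0L), dim(image)))
  }
  hit <- which(seg == label, arr.ind = TRUE)
  loC <- apply(hit, 2, min) - 1L
  hiC <- apply(hit, 2, max)
  ratio <- cfg@coarseSpacing / image@spacing
  lo <- floor(loC * ratio)
  hi <- ceiling(hiC * ratio)
  mv <- ceiling(cfg@bboxMarginMm / image@spacing)
  BoundingBox(pmax(lo - mv, 0), pmin(hi + mv, dim(image)))
}

# nearest-neighbour resampling onto an exact output shape (index-ratio map)
resampleMaskToShape <- function(arr, outShape, ratio) {
  idx <- lapply(1:3, function(a) {
    i <- round((seq_len(outShape[a]) - 1) * ratio[a]) + 1
    pmin(pmax(i, 1L), dim(arr)[a])
  })
  arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

fineCropShape <- function(box, rawSpacing, fineSpacing) {
  pmax(1L, as.integer(round(boxShape(box) * rawSpacing / fineSpacing)))
}

#' Fine-stage segmentation within a bounding box
#'
#' Crops the raw image to the box, resamples the crop to the fine spacing
#' (linear for isotropic inputs, nearest for anisotropic), normalizes,
#' optionally concatenates attention channels, predicts by sliding
#' window, and maps the argmax mask back to the raw grid (nearest
#' neighbour), pasting it into a zero canvas of the original shape --
#' voxels outside the box are always 0.
#'
#' @param image raw [Volume-class].
#' @param box a [BoundingBox-class] from [coarseLocalize()].
#' @param model trained fine `vbnet_model`; its `inChannels` must equal
#'   1 + number of attention channels supplied.
#' @param cfg a [CascadeConfig-class].
#' @param attention optional list of attention map arrays on the fine crop
#'   grid (see [makeOarAttention()], [makeBoundaryAttention()]).
#' @param patchSize fine patch size.
#' @param normSpec normalization; defaults to the model's training
#'   metadata.
#' @return A [LabelMask-class] on the original grid.
#' @export
fineSegment <- function(image, box, model, cfg = CascadeConfig(),
                        attention = NULL, patchSize = c(96L, 96L, 96L),
                        normSpec = NULL) {
  nAtt <- length(attention)
  if (model$spec@inChannels != 1L + nAtt)
    stop(sprintf("fine model was built for %d channels but %d supplied",
                 model$spec@inChannels, 1L + nAtt))
  normSpec <- normSpec %||% normSpecFromMeta(model$meta$normalization)
  crop <- cropVolume(image, box)
  isotropic <- length(unique(image@spacing)) == 1L
  fine <- resampleVolume(crop, cfg@fineSpacing,
                         if (isotropic) "linear" else "nearest")
  xin <- voxelData(normalizeIntensity(fine, normSpec))
  if (nAtt > 0) {
    d <- dim(xin)
    x <- array(0, c(d, 1L + nAtt))
    x[, , , 1] <- xin
    for (i in seq_len(nAtt)) {
      if (!identical(dim(attention[[i]]), d))
        stop("attention map ", i, " does not match the fine crop grid")
      x[, , , 1L + i] <- attention[[i]]
    }
    xin <- x
  }
  probs <- slidingWindowPredict(xin, model, patchSize, cfg@windowOverlap)
  seg <- argmaxClasses(probs)
  # back to raw spacing on the exact box shape
  bs <- boxShape(box)
  segRaw <- resampleMaskToShape(seg, bs, image@spacing / cfg@fineSpacing)
  canvas <- LabelMask(array(0, dim(image)), image@spacing, image@origin)
  pasteVolume(canvas, LabelMask(segRaw, image@spacing), boxLo(box))
}

#' OAR-aware attention map on the fine crop grid
#'
#' Union of the supplied organ-at-risk masks (> 0), cropped to the box and
#' resampled (nearest) to the fine crop grid; values are 0/1.
#'
#' @param oarMasks list of [LabelMask-class] on the original grid.
#' @param box the fine-stage [BoundingBox-class].
#' @param image the raw [Volume-class] (for its geometry).
#' @param cfg a [CascadeConfig-class].
#' @return 3D array in `{0,1}` on the fine crop grid.
#' @export
makeOarAttention <- function(oarMasks, box, image, cfg = CascadeConfig()) {
  outShape <- fineCropShape(box, image@spacing, cfg@fineSpacing)
  if (length(oarMasks) == 0L) return(array(0, outShape))
  u <- NULL
  for (m in oarMasks) {
    if (!identical(dim(m), dim(image)))
      stop("OAR mask geometry does not match the image")
    u <- if (is.null(u)) (m@data > 0) else (u | (m@data > 0))
  }
  cropped <- cropVolume(LabelMask(u * 1, image@spacing, image@origin), box)
  out <- resampleMaskToShape(cropped@data, outShape,
                             image@spacing / cfg@fineSpacing)
  array(as.numeric(out), outShape)
}

#' Boundary-aware attention map on the fine crop grid
#'
#' Encodes the superior-inferior extent prior from the coarse-stage target
#' segmentation: fine-crop slices along the slice axis whose physical
#' position lies within the coarse target's occupied extent get 1, all
#' others 0. The map is constant within each slice.
#'
#' @param box the fine-stage [BoundingBox-class] (raw-grid indices).
#' @param coarseMask the coarse-stage target [LabelMask-class] (on the
#'   coarse grid).
#' @param image the raw [Volume-class].
#' @param cfg a [CascadeConfig-class].
#' @param label target label in the coarse mask.
#' @param sliceAxis slice axis (default 3, superior-inferior).
#' @return 3D array in `{0,1}` on the fine crop grid.
#' @export
makeBoundaryAttention <- function(box, coarseMask, image,
                                  cfg = CascadeConfig(), label = 1L,
                                  sliceAxis = 3L) {
  if (!any(coarseMask@data == label))
    stop("empty coarse target mask: label ", label)
  outShape <- fineCropShape(box, image@spacing, cfg@fineSpacing)
  hit <- which(coarseMask@data == label, arr.ind = TRUE)[, sliceAxis]
  # physical extent of the occupied coarse slices, counting each coarse
  # voxel as a full cell [i*cs, (i+1)*cs) so a mask spanning the whole
  # coarse grid covers every fine slice
  cs <- coarseMask@spacing[sliceAxis]
  zlo <- (min(hit) - 1) * cs
  zhi <- max(hit) * cs
  # physical positions of fine-crop slices
  fs <- cfg@fineSpacing[sliceAxis]
  z0 <- boxLo(box)[sliceAxis] * image@spacing[sliceAxis]
  zf <- z0 + (seq_len(outShape[sliceAxis]) - 1) * fs
  ind <- as.numeric(zf >= zlo & zf < zhi)
  out <- array(0, outShape)
  if (sliceAxis == 1L) out[] <- ind
  else if (sliceAxis == 2L) out[] <- rep(rep(ind, each = outShape[1]),
                                         times = outShape[3])
  else out[] <- rep(ind, each = outShape[1] * outShape[2])
  out
}

#' Connected-component post-processing
#'
#' Per label: keep only the largest 26-connected component
#' (`keepLargestCC`), or remove components smaller than `minCCVoxels`.
#' Never adds voxels; idempotent; an empty mask passes through.
#'
#' @param mask a [LabelMask-class].
#' @param cfg a [CascadeConfig-class].
#' @return The filtered [LabelMask-class].
#' @export
postProcess <- function(mask, cfg = CascadeConfig()) {
  d <- mask@data
  for (k in setdiff(sort(unique(as.vector(d))), 0)) {
    bin <- (d == k) * 1L
    comps <- cpp_label_components(as.integer(bin), dim(d))
    nc <- max(comps)
    if (nc <= 0L) next
    sizes <- tabulate(comps[comps > 0], nbins = nc)
    drop <- if (cfg@keepLargestCC) which(sizes < max(sizes)) else
      which(sizes < cfg@minCCVoxels)
    if (cfg@keepLargestCC && length(which(sizes == max(sizes))) > 1L) {
      # deterministic tie-break: keep the first component found in scan order
      keep <- which(sizes == max(sizes))[1]
      drop <- setdiff(seq_len(nc), keep)
    }
    if (length(drop)) d[array(comps %in% drop, dim(d))] <- 0
  }
  LabelMask(d, mask@spacing, mask@origin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full coarse-to-fine cascade on one image
#'
#' Coarse localization, optional attention-map construction, fine
#' segmentation inside the box, and connected-component post-processing.
#' The report records the box, per-stage timings and voxel counts.
#'
#' @param image raw [Volume-class].
#' @param coarseModel,fineModel trained `vbnet_model`s (the fine model's
#'   `inChannels` must match the configured attention channels).
#' @param cfg a [CascadeConfig-class].
#' @param oarMasks list of [LabelMask-class] for the OAR-aware attention
#'   channel (required when `cfg@useOarMap`).
#' @param label structure label to segment.
#' @param coarsePatchSize,finePatchSize stage patch sizes.
#' @return list(mask = [LabelMask-class], report = list).
#' @export
runCascade <- function(image, coarseModel, fineModel, cfg = CascadeConfig(),
                       oarMasks = NULL, label = 1L,
                       coarsePatchSize = c(96L, 96L, 96L),
                       finePatchSize = c(96L, 96L, 96L)) {
  nAtt <- as.integer(cfg@useOarMap) + as.integer(cfg@useBoundaryMap)
  if (fineModel$spec@inChannels != 1L + nAtt)
    stop(sprintf(
      "configuration error: fine model has %d input channels but config implies %d",
      fineModel$spec@inChannels, 1L + nAtt))
  if (cfg@useOarMap && length(oarMasks) == 0L)
    stop("configuration error: useOarMap requires oarMasks")
  report <- list()
  t0 <- proc.time()[["elapsed"]]
  box <- coarseLocalize(image, coarseModel, cfg, label, coarsePatchSize)
  t1 <- proc.time()[["elapsed"]]
  attention <- list()
  coarseSeg <- NULL
  if (cfg@useBoundaryMap) {
    lowres <- resampleVolume(image, cfg@coarseSpacing, "nearest")
    xin <- normalizeIntensity(lowres,
                              normSpecFromMeta(coarseModel$meta$normalization))
    probs <- slidingWindowPredict(voxelData(xin), coarseModel,
                                  coarsePatchSize, cfg@windowOverlap)
    coarseSeg <- LabelMask(argmaxClasses(probs), cfg@coarseSpacing)
    if (any(coarseSeg@data == label))
      attention$boundary <- makeBoundaryAttention(box, coarseSeg, image, cfg,
                                                  label)
    else
      attention$boundary <- array(1, fineCropShape(box, image@spacing,
                                                   cfg@fineSpacing))
  }
  if (cfg@useOarMap)
    attention$oar <- makeOarAttention(oarMasks, box, image, cfg)
  # order: raw image, OAR map, boundary map
  attention <- attention[intersect(c("oar", "boundary"), names(attention))]
  mask <- fineSegment(image, box, fineModel, cfg, attention, finePatchSize)
  t2 <- proc.time()[["elapsed"]]
  mask <- postProcess(mask, cfg)
  t3 <- proc.time()[["elapsed"]]
  report$box <- list(lo = boxLo(box), hi = boxHi(box))
  report$seconds <- c(coarse = t1 - t0, fine = t2 - t1, postprocess = t3 - t2)
  report$voxels <- c(box = prod(boxShape(box)),
                     predicted = sum(mask@data == label))
  list(mask = mask, report = report)
}
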