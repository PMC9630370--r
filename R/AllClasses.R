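#' @import methods
#' @importFrom stats quantile rnorm runif sd setNames
#' @importFrom utils write.csv head tail
#' @useDynLib vbcascade, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Geometric volume types
# ---------------------------------------------------------------------------

#' Volume: a 3D scalar grid with voxel geometry
#'
#' A `Volume` carries a 3D array of real-valued intensities together with its
#' voxel spacing (mm) and the physical coordinate of voxel (0,0,0). Geometry
#' is axis-aligned: the physical position of voxel (i,j,k), 0-based, is
#' `origin + (i*sx, j*sy, k*sz)`. Direction matrices (oblique acquisitions)
#' are out of scope and rejected at read time.
#'
#' @slot data 3D numeric array of intensities.
#' @slot spacing numeric length-3, voxel spacing in mm, all > 0.
#' @slot origin numeric length-3, physical coordinate of voxel (0,0,0) in mm.
#' @export
setClass("Volume",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3D array")
    if (length(object@spacing) != 3L || !all(is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 strictly positive finite values")
    if (length(object@origin) != 3L || !all(is.finite(object@origin)))
      msg <- c(msg, "origin must be 3 finite values")
    if (length(msg)) msg else TRUE
  })

#' LabelMask: a 3D integer grid sharing Volume geometry
#'
#' Values are non-negative integers; 0 is background and k >= 1 is the k-th
#' structure. A `LabelMask` is a `Volume` whose data are whole numbers.
#'
#' @export
setClass("LabelMask", contains = "Volume",
  validity = function(object) {
    d <- object@data
    if (any(d < 0) || max(abs(d - round(d))) > 0)
      return("label values must be non-negative integers")
    TRUE
  })

#' BoundingBox: axis-aligned half-open voxel-index box
#'
#' Indices are 0-based; `lo` is inclusive and `hi` exclusive, so the box
#' shape is `hi - lo` and boxes compose cleanly with crop/paste.
#'
#' @slot lo integer length-3, inclusive lower corner.
#' @slot hi integer length-3, exclusive upper corner.
#' @export
setClass("BoundingBox",
  representation(lo = "integer", hi = "integer"),
  validity = function(object) {
    if (length(object@lo) != 3L || length(object@hi) != 3L)
      return("lo and hi must have length 3")
    if (any(object@hi <= object@lo))
      return("box must satisfy lo < hi componentwise")
    TRUE
  })

#' NormalizationSpec: CT window or MRI percentile z-score normalization
#'
#' CT mode maps `x` to `clip((x - windowLevel) / (windowWidth/2), -1, 1)`.
#' MRI mode clips to the `[lowerPct, upperPct]` percentile band, subtracts
#' the band mean and divides by the band SD, then clips to `[-1, 1]`.
#'
#' @slot mode `"ct_window"` or `"mri_percentile"`.
#' @slot windowLevel,windowWidth CT window centre and width (width > 0).
#' @slot lowerPct,upperPct MRI percentile band in `[0, 100]`.
#' @export
setClass("NormalizationSpec",
  representation(mode = "character", windowLevel = "numeric",
                 windowWidth = "numeric", lowerPct = "numeric",
                 upperPct = "numeric"),
  prototype(mode = "ct_window", windowLevel = 40, windowWidth = 400,
            lowerPct = 0.5, upperPct = 99.5),
  validity = function(object) {
    if (!object@mode %in% c("ct_window", "mri_percentile"))
      return("mode must be 'ct_window' or 'mri_percentile'")
    if (object@mode == "ct_window" && object@windowWidth <= 0)
      return("windowWidth must be > 0")
    if (object@mode == "mri_percentile" &&
        !(object@lowerPct < object@upperPct &&
          object@lowerPct >= 0 && object@upperPct <= 100))
      return("percentiles must satisfy 0 <= lowerPct < upperPct <= 100")
    TRUE
  })

# ---------------------------------------------------------------------------
# Phantom specification
# ---------------------------------------------------------------------------

#' PhantomSpec: synthetic CT-like phantom description
#'
#' A phantom is a body ellipsoid embedded in air-analog background, with K
#' organ ellipsoids of distinct mean intensity inside it, plus additive
#' Gaussian noise. Ellipsoids are defined in physical (mm) coordinates so
#' voxel counts can be checked against closed-form volumes.
#'
#' @slot shape integer length-3 grid shape.
#' @slot spacing numeric length-3 voxel spacing (mm).
#' @slot body list with `center`, `semiAxes` (mm) and `intensity`.
#' @slot organs list of lists with `label`, `center`, `semiAxes`,
#'   `intensity`; labels must be contiguous 1..K, later organs override
#'   earlier ones on overlap.
#' @slot background numeric, intensity outside the body (air analog).
#' @slot noiseSd numeric >= 0, SD of additive Gaussian noise.
#' @slot seed integer seed making generation deterministic.
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", spacing = "numeric", body = "list",
                 organs = "list", background = "numeric", noiseSd = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@shape) != 3L || any(object@shape < 1))
      msg <- c(msg, "shape must be 3 positive integers")
    if (any(object@spacing <= 0)) msg <- c(msg, "spacing must be positive")
    labs <- vapply(object@organs, function(o) o$label, numeric(1))
    if (length(labs) && !identical(sort(labs), as.numeric(seq_along(labs))))
      msg <- c(msg, "organ labels must be unique and contiguous 1..K")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    for (o in object@organs) {
      # analytic containment (sufficient, via the triangle inequality in the
      # body-normalized norm): ||(c_o - c_b)/A_b|| + max(a_o/A_b) <= 1
      d <- sqrt(sum(((o$center - object@body$center) / object@body$semiAxes)^2))
      if (d + max(o$semiAxes / object@body$semiAxes) > 1 + 1e-9)
        msg <- c(msg, sprintf("organ %d extends outside the body", o$label))
    }
    if (length(msg)) msg else TRUE
  })

# ---------------------------------------------------------------------------
# Network / loss / training / cascade configuration
# ---------------------------------------------------------------------------

#' NetworkSpec: declarative description of a VB-Net
#'
#' `levels` counts down-sampling steps: a spec with `levels = L` has L+1
#' resolution levels and halves each spatial dimension L times, so patch
#' sides must be divisible by `2^L` (by `2^(L+1)` with the adaptive input
#' module, which adds one more learned down/up-sampling pair).
#'
#' @slot inChannels integer >= 1 input channels (1 + attention channels).
#' @slot outClasses integer >= 2 output classes (background included).
#' @slot levels integer >= 1 down-sampling steps.
#' @slot baseChannels integer, channels at the finest level; doubled per
#'   level and capped at 16x base.
#' @slot bottlenecksPerBlock integer vector, bottleneck residual units per
#'   down/up block (length `2*levels`, or length 1 to recycle).
#' @slot adaptiveInput logical, prepend/append the learned stride-2
#'   resampling pair.
#' @export
setClass("NetworkSpec",
  representation(inChannels = "integer", outClasses = "integer",
                 levels = "integer", baseChannels = "integer",
                 bottlenecksPerBlock = "integer", adaptiveInput = "logical"),
  prototype(inChannels = 1L, outClasses = 2L, levels = 3L,
            baseChannels = 8L, bottlenecksPerBlock = 1L,
            adaptiveInput = FALSE),
  validity = function(object) {
    msg <- character()
    if (object@inChannels < 1L) msg <- c(msg, "inChannels must be >= 1")
    if (object@outClasses < 2L) msg <- c(msg, "outClasses must be >= 2")
    if (object@levels < 1L) msg <- c(msg, "levels must be >= 1")
    if (object@baseChannels < 1L) msg <- c(msg, "baseChannels must be >= 1")
    nb <- length(object@bottlenecksPerBlock)
    if (!nb %in% c(1L, 2L * object@levels))
      msg <- c(msg, sprintf(
        "bottlenecksPerBlock must have length 1 or %d (one per down/up block)",
        2L * object@levels))
    if (any(object@bottlenecksPerBlock < 0L))
      msg <- c(msg, "bottleneck counts must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' LossConfig: weights and options of the training objective
#'
#' Houses the multi-dimensional adaptive loss weights (`lambda1` for the 3D
#' Dice term, `lambda2` for the adaptively weighted per-slice 2D Dice sum),
#' the smoothing constant added to Dice numerator and denominator, the
#' boundary band width for boundary Dice, and the slice axis (default the
#' third, superior-inferior, axis).
#'
#' @slot lambda1,lambda2 non-negative weights (defaults 0.7 and 0.3).
#' @slot smoothEps small positive smoothing constant (default 1e-5).
#' @slot boundaryWidthVox integer >= 1 boundary shell width (default 2).
#' @slot sliceAxis slice axis index in 1..3 (default 3).
#' @slot components character subset of
#'   `c("dice3d", "boundary_dice", "adaptive2d", "focal")`.
#' @slot averageSlices logical; if TRUE the slice terms are averaged rather
#'   than summed (off by default: the sum is the printed form).
#' @slot focalGamma,focalAlpha focal-loss parameters.
#' @export
setClass("LossConfig",
  representation(lambda1 = "numeric", lambda2 = "numeric",
                 smoothEps = "numeric", boundaryWidthVox = "integer",
                 sliceAxis = "integer", components = "character",
                 averageSlices = "logical", focalGamma = "numeric",
                 focalAlpha = "numeric"),
  prototype(lambda1 = 0.7, lambda2 = 0.3, smoothEps = 1e-5,
            boundaryWidthVox = 2L, sliceAxis = 3L,
            components = c("dice3d", "adaptive2d"), averageSlices = FALSE,
            focalGamma = 2, focalAlpha = 1),
  validity = function(object) {
    msg <- character()
    if (object@lambda1 < 0 || object@lambda2 < 0)
      msg <- c(msg, "lambda1 and lambda2 must be >= 0")
    if (object@smoothEps <= 0) msg <- c(msg, "smoothEps must be > 0")
    if (!object@sliceAxis %in% 1:3) msg <- c(msg, "sliceAxis must be in 1..3")
    if (object@boundaryWidthVox < 1L)
      msg <- c(msg, "boundaryWidthVox must be >= 1")
    bad <- setdiff(object@components,
                   c("dice3d", "boundary_dice", "adaptive2d", "focal"))
    if (length(bad)) msg <- c(msg, paste("unknown loss components:",
                                         paste(bad, collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

#' SamplerConfig: patch sampling scheme
#'
#' Global sampling draws patch centres uniformly over the image foreground
#' (normalized intensity above `foregroundThreshold`); mask sampling draws
#' them uniformly inside the labelled region. Both schemes can be mixed
#' 50/50 with `scheme = "mixed"`.
#'
#' @slot scheme one of `"global"`, `"mask"`, `"mixed"`.
#' @slot patchSize integer length-3 patch shape.
#' @slot batchSize integer >= 2 patches per mini-batch.
#' @slot foregroundThreshold normalized intensity defining foreground for
#'   global sampling (default -0.9, i.e. anything above the air floor).
#' @export
setClass("SamplerConfig",
  representation(scheme = "character", patchSize = "integer",
                 batchSize = "integer", foregroundThreshold = "numeric"),
  prototype(scheme = "global", patchSize = c(96L, 96L, 96L), batchSize = 2L,
            foregroundThreshold = -0.9),
  validity = function(object) {
    msg <- character()
    if (!object@scheme %in% c("global", "mask", "mixed"))
      msg <- c(msg, "scheme must be 'global', 'mask' or 'mixed'")
    if (length(object@patchSize) != 3L || any(object@patchSize < 1L))
      msg <- c(msg, "patchSize must be 3 positive integers")
    if (object@batchSize < 2L)
      msg <- c(msg, "batchSize must be at least 2")
    if (length(msg)) msg else TRUE
  })

#' TrainConfig: optimization loop settings
#'
#' Defaults follow the recommended configuration: up to 1000 epochs, Adam
#' with initial learning rate 1e-4, betas (0.9, 0.999) and decoupled weight
#' decay 1e-4, a step learning-rate schedule (factor 0.1 every 250 epochs),
#' a 10 percent validation split, and early stopping once the validation
#' loss has not decreased (tolerance 1e-6) for 5 consecutive epochs.
#'
#' @slot epochs maximum epochs.
#' @slot lrInitial initial learning rate.
#' @slot lrFactor,lrInterval step schedule: lr is multiplied by `lrFactor`
#'   every `lrInterval` epochs.
#' @slot weightDecay decoupled weight decay.
#' @slot beta1,beta2 Adam moment decay rates.
#' @slot valFraction fraction of cases held out for validation.
#' @slot patienceEpochs early-stopping patience.
#' @slot batchesPerCase sampled mini-batches per training case per epoch
#'   (patch sampling has no natural epoch; this fixes the epoch size).
#' @slot augmentation character subset of
#'   `c("rotate", "scale", "flip", "shift", "noise")`.
#' @slot seed integer seed for all training randomness.
#' @export
setClass("TrainConfig",
  representation(epochs = "integer", lrInitial = "numeric",
                 lrFactor = "numeric", lrInterval = "integer",
                 weightDecay = "numeric", beta1 = "numeric", beta2 = "numeric",
                 valFraction = "numeric", patienceEpochs = "integer",
                 batchesPerCase = "integer", augmentation = "character",
                 seed = "integer"),
  prototype(epochs = 1000L, lrInitial = 1e-4, lrFactor = 0.1,
            lrInterval = 250L, weightDecay = 1e-4, beta1 = 0.9, beta2 = 0.999,
            valFraction = 0.10, patienceEpochs = 5L, batchesPerCase = 4L,
            augmentation = character(), seed = 1L),
  validity = function(object) {
    msg <- character()
    if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
    if (object@lrInitial <= 0) msg <- c(msg, "lrInitial must be > 0")
    if (object@valFraction <= 0 || object@valFraction >= 1)
      msg <- c(msg, "valFraction must be in (0, 1)")
    if (object@patienceEpochs < 1L) msg <- c(msg, "patienceEpochs must be >= 1")
    bad <- setdiff(object@augmentation,
                   c("rotate", "scale", "flip", "shift", "noise"))
    if (length(bad)) msg <- c(msg, paste("unknown augmentations:",
                                         paste(bad, collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

#' CascadeConfig: two-stage inference settings
#'
#' @slot coarseSpacing,fineSpacing target spacings (mm) of the two stages;
#'   defaults 5 mm isotropic (coarse) and 1 mm isotropic (fine). Coarse
#'   spacing must be >= fine spacing componentwise.
#' @slot bboxMarginMm non-negative margin (mm) added around the coarse box.
#' @slot windowOverlap sliding-window overlap fraction in `[0, 1)`.
#' @slot keepLargestCC keep only the largest 26-connected component.
#' @slot minCCVoxels remove components smaller than this (ignored when
#'   `keepLargestCC`); default 27 voxels (~3 mm cube at 1 mm).
#' @slot useOarMap,useBoundaryMap attention channels for the fine model.
#' @slot strictCoarse if TRUE, coarse detection failure is an error;
#'   otherwise fall back to the whole-image box with a warning.
#' @export
setClass("CascadeConfig",
  representation(coarseSpacing = "numeric", fineSpacing = "numeric",
                 bboxMarginMm = "numeric", windowOverlap = "numeric",
                 keepLargestCC = "logical", minCCVoxels = "integer",
                 useOarMap = "logical", useBoundaryMap = "logical",
                 strictCoarse = "logical"),
  prototype(coarseSpacing = c(5, 5, 5), fineSpacing = c(1, 1, 1),
            bboxMarginMm = c(10, 10, 10), windowOverlap = 0,
            keepLargestCC = TRUE, minCCVoxels = 27L,
            useOarMap = FALSE, useBoundaryMap = FALSE, strictCoarse = FALSE),
  validity = function(object) {
    msg <- character()
    if (any(object@coarseSpacing < object@fineSpacing))
      msg <- c(msg, "coarseSpacing must be >= fineSpacing componentwise")
    if (any(object@bboxMarginMm < 0)) msg <- c(msg, "bboxMarginMm must be >= 0")
    if (object@windowOverlap < 0 || object@windowOverlap >= 1)
      msg <- c(msg, "windowOverlap must be in [0, 1)")
    if (object@minCCVoxels < 0L) msg <- c(msg, "minCCVoxels must be >= 0")
    if (length(msg)) msg else TRUE
  })
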