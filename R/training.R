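# Patch sampling, augmentation, the Adam training loop and early stopping.

#' Construct a SamplerConfig
#'
#' @param scheme `"global"` (centers uniform over image foreground),
#'   `"mask"` (uniform over labelled voxels) or `"mixed"` (50/50).
#' @param patchSize patch shape (length 3 or 1).
#' @param batchSize patches per mini-batch (>= 2).
#' @param foregroundThreshold normalized-intensity floor defining the
#'   foreground space for global sampling.
#' @return A [SamplerConfig-class].
#' @export
SamplerConfig <- function(scheme = "global", patchSize = c(96L, 96L, 96L),
                          batchSize = 2L, foregroundThreshold = -0.9) {
  if (length(patchSize) == 1L) patchSize <- rep(patchSize, 3L)
  new("SamplerConfig", scheme = scheme, patchSize = as.integer(patchSize),
      batchSize = as.integer(batchSize),
      foregroundThreshold = foregroundThreshold)
}

#' Construct a TrainConfig
#'
#' @param epochs,lrInitial,lrFactor,lrInterval,weightDecay,beta1,beta2
#'   optimizer settings; see [TrainConfig-class] for defaults.
#' @param valFraction,patienceEpochs validation split and early-stopping
#'   patience.
#' @param batchesPerCase mini-batches sampled per case per epoch.
#' @param augmentation subset of
#'   `c("rotate", "scale", "flip", "shift", "noise")`.
#' @param seed master seed of the run.
#' @return A [TrainConfig-class].
#' @export
TrainConfig <- function(epochs = 1000L, lrInitial = 1e-4, lrFactor = 0.1,
                        lrInterval = 250L, weightDecay = 1e-4, beta1 = 0.9,
                        beta2 = 0.999, valFraction = 0.10, patienceEpochs = 5L,
                        batchesPerCase = 4L, augmentation = character(),
                        seed = 1L) {
  new("TrainConfig", epochs = as.integer(epochs), lrInitial = lrInitial,
      lrFactor = lrFactor, lrInterval = as.integer(lrInterval),
      weightDecay = weightDecay, beta1 = beta1, beta2 = beta2,
      valFraction = valFraction, patienceEpochs = as.integer(patienceEpochs),
      batchesPerCase = as.integer(batchesPerCase), augmentation = augmentation,
      seed = as.integer(seed))
}

#' Construct a LossConfig
#'
#' @param lambda1,lambda2,smoothEps,boundaryWidthVox,sliceAxis,components,averageSlices,focalGamma,focalAlpha
#'   see [LossConfig-class].
#' @export
LossConfig <- function(lambda1 = 0.7, lambda2 = 0.3, smoothEps = 1e-5,
                       boundaryWidthVox = 2L, sliceAxis = 3L,
                       components = c("dice3d", "adaptive2d"),
                       averageSlices = FALSE, focalGamma = 2, focalAlpha = 1) {
  new("LossConfig", lambda1 = lambda1, lambda2 = lambda2,
      smoothEps = smoothEps, boundaryWidthVox = as.integer(boundaryWidthVox),
      sliceAxis = as.integer(sliceAxis), components = components,
      averageSlices = averageSlices, focalGamma = focalGamma,
      focalAlpha = focalAlpha)
}

# ---- patch sampling --------------------------------------------------------

#' Sample patch centre points
#'
#' Global sampling draws centres uniformly (with replacement) over voxels
#' whose normalized intensity exceeds `cfg@foregroundThreshold`; mask
#' sampling draws uniformly over `mask > 0`; `"mixed"` alternates 50/50.
#'
#' @param image normalized [Volume-class].
#' @param mask [LabelMask-class] on the same grid.
#' @param cfg a [SamplerConfig-class].
#' @param n number of centres.
#' @return n x 3 matrix of 1-based voxel indices.
#' @export
samplePatchCenters <- function(image, mask, cfg, n) {
  pick <- function(scheme, m) {
    cand <- if (scheme == "mask") which(mask@data > 0)
            else which(image@data > cfg@foregroundThreshold)
    if (length(cand) == 0L)
      stop("empty candidate set for ", scheme, " sampling")
    cand[sample.int(length(cand), m, replace = TRUE)]
  }
  idx <- switch(cfg@scheme,
    global = pick("global", n),
    mask = pick("mask", n),
    mixed = {
      ng <- n %/% 2L
      c(pick("global", ng), pick("mask", n - ng))
    })
  arrayInd(idx, dim(image@data))
}

#' Extract an aligned image/label patch around a centre
#'
#' The patch has exactly `patchSize` voxels; regions falling outside the
#' grid are padded with -1 in the (normalized) image and 0 in the labels.
#'
#' @param image normalized [Volume-class].
#' @param mask [LabelMask-class] on the same grid.
#' @param center 1-based voxel index (length 3).
#' @param patchSize patch shape.
#' @return list(x = image patch array, y = label patch array).
#' @export
extractPatch <- function(image, mask, center, patchSize) {
  if (length(patchSize) == 1L) patchSize <- rep(patchSize, 3L)
  d <- dim(image@data)
  start <- as.integer(center) - patchSize %/% 2L      # 1-based
  x <- array(-1, patchSize)
  y <- array(0, patchSize)
  srcLo <- pmax(start, 1L); srcHi <- pmin(start + patchSize - 1L, d)
  if (all(srcHi >= srcLo)) {
    dstLo <- srcLo - start + 1L; dstHi <- srcHi - start + 1L
    x[dstLo[1]:dstHi[1], dstLo[2]:dstHi[2], dstLo[3]:dstHi[3]] <-
      image@data[srcLo[1]:srcHi[1], srcLo[2]:srcHi[2], srcLo[3]:srcHi[3]]
    y[dstLo[1]:dstHi[1], dstLo[2]:dstHi[2], dstLo[3]:dstHi[3]] <-
      mask@data[srcLo[1]:srcHi[1], srcLo[2]:srcHi[2], srcLo[3]:srcHi[3]]
  }
  list(x = x, y = y)
}

# general (non-separable) coordinate sampling with constant padding;
# coords are 0-based continuous indices as arrays of equal shape
sampleAtCoords <- function(a, cx, cy, cz, method = "linear", pad = 0) {
  d <- dim(a)
  valid <- cx > -0.5 & cx < d[1] - 0.5 & cy > -0.5 & cy < d[2] - 0.5 &
    cz > -0.5 & cz < d[3] - 0.5
  out <- array(pad, dim(cx))
  if (!any(valid)) return(out)
  cxv <- pmin(pmax(cx[valid], 0), d[1] - 1)
  cyv <- pmin(pmax(cy[valid], 0), d[2] - 1)
  czv <- pmin(pmax(cz[valid], 0), d[3] - 1)
  if (method == "nearest") {
    out[valid] <- a[cbind(round(cxv) + 1, round(cyv) + 1, round(czv) + 1)]
  } else {
    x0 <- pmin(floor(cxv), d[1] - 1); fx <- cxv - x0
    y0 <- pmin(floor(cyv), d[2] - 1); fy <- cyv - y0
    z0 <- pmin(floor(czv), d[3] - 1); fz <- czv - z0
    x1 <- pmin(x0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1)
    z1 <- pmin(z0 + 1, d[3] - 1)
    g <- function(ix, iy, iz) a[cbind(ix + 1, iy + 1, iz + 1)]
    out[valid] <-
      g(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
      g(x1, y0, z0) * fx * (1 - fy) * (1 - fz) +
      g(x0, y1, z0) * (1 - fx) * fy * (1 - fz) +
      g(x1, y1, z0) * fx * fy * (1 - fz) +
      g(x0, y0, z1) * (1 - fx) * (1 - fy) * fz +
      g(x1, y0, z1) * fx * (1 - fy) * fz +
      g(x0, y1, z1) * (1 - fx) * fy * fz +
      g(x1, y1, z1) * fx * fy * fz
  }
  out
}

#' Jointly augment an image/label patch pair
#'
#' Applies one random spatial transform (rotation about the slice axis up
#' to +/-10 degrees, isotropic scaling 0.9-1.1, axis flips, integer shifts
#' up to +/-5 voxels) identically to image and labels -- trilinear for the
#' image, nearest-neighbour for labels -- and additive Gaussian noise
#' (SD 0.02 in normalized units) to the image only. An empty augmentation
#' set returns the inputs unchanged (bit-identical).
#'
#' @param x,y image and label patch arrays of equal shape.
#' @param augmentation character subset of
#'   `c("rotate", "scale", "flip", "shift", "noise")`.
#' @param ranges list overriding `rotateDeg`, `scaleRange`, `shiftVox`,
#'   `noiseSd`.
#' @return list(x, y) of augmented patches.
#' @export
augmentPatch <- function(x, y, augmentation,
                         ranges = list(rotateDeg = 10, scaleRange = c(0.9, 1.1),
                                       shiftVox = 5, noiseSd = 0.02)) {
  if (length(augmentation) == 0L) return(list(x = x, y = y))
  d <- dim(x)
  doAffine <- any(c("rotate", "scale", "shift") %in% augmentation)
  if ("flip" %in% augmentation) {
    for (ax in 1:3) {
      if (runif(1) < 0.5) {
        idx <- rev(seq_len(d[ax]))
        if (ax == 1) { x <- x[idx, , , drop = FALSE]; y <- y[idx, , , drop = FALSE] }
        else if (ax == 2) { x <- x[, idx, , drop = FALSE]; y <- y[, idx, , drop = FALSE] }
        else { x <- x[, , idx, drop = FALSE]; y <- y[, , idx, drop = FALSE] }
      }
    }
  }
  if (doAffine) {
    theta <- if ("rotate" %in% augmentation)
      runif(1, -ranges$rotateDeg, ranges$rotateDeg) * pi / 180 else 0
    sc <- if ("scale" %in% augmentation)
      runif(1, ranges$scaleRange[1], ranges$scaleRange[2]) else 1
    sh <- if ("shift" %in% augmentation)
      round(runif(3, -ranges$shiftVox, ranges$shiftVox)) else c(0, 0, 0)
    ctr <- (d - 1) / 2
    # target grid, 0-based
    gi <- array(rep(0:(d[1] - 1), times = d[2] * d[3]), d) - ctr[1] - sh[1]
    gj <- array(rep(rep(0:(d[2] - 1), each = d[1]), times = d[3]), d) - ctr[2] - sh[2]
    gk <- array(rep(0:(d[3] - 1), each = d[1] * d[2]), d) - ctr[3] - sh[3]
    # inverse map: un-scale then un-rotate (rotation in the i-j plane)
    ui <- gi / sc; uj <- gj / sc; uk <- gk / sc
    cx <- cos(-theta) * ui - sin(-theta) * uj + ctr[1]
    cy <- sin(-theta) * ui + cos(-theta) * uj + ctr[2]
    cz <- uk + ctr[3]
    x <- sampleAtCoords(x, cx, cy, cz, "linear", pad = -1)
    y <- sampleAtCoords(y, cx, cy, cz, "nearest", pad = 0)
    dim(x) <- d; dim(y) <- d
  }
  if ("noise" %in% augmentation)
    x <- x + array(rnorm(length(x), 0, ranges$noiseSd), d)
  list(x = x, y = y)
}

#' Split cases into training and validation sets
#'
#' Disjoint and exhaustive; the validation set has
#' `max(1, round(valFraction * N))` cases.
#'
#' @param cases list or vector of cases (>= 2).
#' @param valFraction fraction held out (default 0.10).
#' @param seed integer seed.
#' @return list(train, val).
#' @export
splitTrainVal <- function(cases, valFraction = 0.10, seed = 1L) {
  n <- length(cases)
  if (n < 2L) stop("need at least 2 cases to split")
  nVal <- max(1L, round(valFraction * n))
  if (nVal >= n) nVal <- n - 1L
  vi <- withLocalSeed(seed, sample.int(n, nVal))
  list(train = cases[setdiff(seq_len(n), vi)], val = cases[vi])
}

#' Early-stopping decision on a loss sequence
#'
#' Improvement means a strict decrease below the best-so-far by more than
#' `tol`; training stops once `patience` consecutive epochs bring no
#' improvement.
#'
#' @param losses per-epoch validation losses, in order.
#' @param patience consecutive non-improving epochs tolerated.
#' @param tol improvement tolerance.
#' @return list(stopEpoch, bestEpoch, stopped).
#' @export
stoppingEpoch <- function(losses, patience = 5L, tol = 1e-6) {
  best <- Inf; bestEpoch <- 0L; since <- 0L
  for (e in seq_along(losses)) {
    if (losses[e] < best - tol) {
      best <- losses[e]; bestEpoch <- e; since <- 0L
    } else since <- since + 1L
    if (since >= patience)
      return(list(stopEpoch = e, bestEpoch = bestEpoch, stopped = TRUE))
  }
  list(stopEpoch = length(losses), bestEpoch = bestEpoch, stopped = FALSE)
}

# ---- composite loss on class probabilities --------------------------------

# loss and probability-space gradient for one foreground class
classLossGrad <- function(pk, tk, cfg) {
  loss <- 0
  grad <- array(0, dim(pk))
  if ("adaptive2d" %in% cfg@components) {
    loss <- loss + adaptiveLoss(pk, tk, cfg)
    grad <- grad + adaptiveLossGrad(pk, tk, cfg)
  } else if ("dice3d" %in% cfg@components) {
    loss <- loss + diceLoss3D(pk, tk, cfg@smoothEps)
    grad <- grad + diceLoss3DGrad(pk, tk, cfg@smoothEps)
  }
  if ("boundary_dice" %in% cfg@components) {
    loss <- loss + suppressWarnings(boundaryDiceLoss(pk, tk, cfg))
    grad <- grad + boundaryDiceLossGrad(pk, tk, cfg)
  }
  if ("focal" %in% cfg@components) {
    loss <- loss + focalLoss(pk, tk, cfg@focalGamma, cfg@focalAlpha)
    grad <- grad + focalLossGrad(pk, tk, cfg@focalGamma, cfg@focalAlpha)
  }
  list(loss = loss, grad = grad)
}

# composite loss over all foreground classes; returns loss and the
# gradient in class-score space (through the softmax)
batchLossGrad <- function(scores, y, cfg, withGrad = TRUE) {
  probs <- softmaxChannels(scores)
  K <- dim(probs)[4] - 1L
  gp <- array(0, dim(probs))
  total <- 0
  for (k in seq_len(K)) {
    pk <- probs[, , , k + 1]
    tk <- (y == k) * 1
    lg <- classLossGrad(pk, tk, cfg)
    total <- total + lg$loss / K
    if (withGrad) gp[, , , k + 1] <- lg$grad / K
  }
  list(loss = total,
       gscores = if (withGrad) softmaxBw(probs, gp) else NULL,
       probs = probs)
}

# ---- Adam ------------------------------------------------------------------

adamInit <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

# decoupled weight decay applied to convolution weights only
adamStep <- function(params, grads, state, lr, beta1, beta2, wd,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    step <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (wd > 0 && grepl("\\.(w|tw)$", nm))
      step <- step + wd * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * step
  }
  list(params = params, state = state)
}

# ---- training loop ---------------------------------------------------------

loadCase <- function(case) {
  if (is.character(case)) {
    list(image = readVolume(file.path(case, "image.nii.gz")),
         label = readVolume(file.path(case, "label.nii.gz"), label = TRUE))
  } else case
}

prepCase <- function(case, targetSpacing, normSpec, resampleMethod) {
  case <- loadCase(case)
  img <- case$image; lab <- case$label
  if (!is.null(targetSpacing)) {
    img <- resampleVolume(img, targetSpacing, resampleMethod)
    lab <- resampleVolume(lab, targetSpacing, "nearest")
  }
  list(image = normalizeIntensity(img, normSpec), label = lab)
}

drawBatch <- function(case, samplerCfg, augmentation) {
  centers <- samplePatchCenters(case$image, case$label, samplerCfg,
                                samplerCfg@batchSize)
  lapply(seq_len(nrow(centers)), function(i) {
    p <- extractPatch(case$image, case$label, centers[i, ],
                      samplerCfg@patchSize)
    augmentPatch(p$x, p$y, augmentation)
  })
}

#' Train a VB-Net on image/label cases
#'
#' Cases are resampled to `targetSpacing`, normalized, and sampled into
#' aligned patches per the sampler configuration. Each epoch draws
#' `batchesPerCase` mini-batches (each of at least 2 patches) per training
#' case, optimizes the configured loss with Adam under the step
#' learning-rate schedule, and evaluates the loss on a fixed set of
#' validation patches at epoch end. Training stops at `epochs` or when the
#' validation loss has not decreased (tolerance 1e-6) for
#' `patienceEpochs` consecutive epochs; the best-validation parameters are
#' kept. With all seeds fixed the run is bit-reproducible in
#' single-threaded mode.
#'
#' @param trainCases,valCases lists of cases: either case-directory paths
#'   (with `image.nii.gz` / `label.nii.gz`) or lists with `image` and
#'   `label` elements.
#' @param netSpec a [NetworkSpec-class].
#' @param lossCfg a [LossConfig-class].
#' @param trainCfg a [TrainConfig-class].
#' @param samplerCfg a [SamplerConfig-class].
#' @param normSpec a [NormalizationSpec-class] applied to every case.
#' @param targetSpacing stage spacing (mm); NULL keeps native spacing.
#' @param resampleMethod image interpolation for the stage resampling.
#' @param checkpointDir if non-NULL, the best model is saved there.
#' @param verbose print per-epoch losses.
#' @return list(model, log, stopEpoch, bestEpoch); `log` is a data.frame
#'   with epoch, train_loss, val_loss, val_dice, lr.
#' @export
trainModel <- function(trainCases, valCases, netSpec,
                       lossCfg = LossConfig(), trainCfg = TrainConfig(),
                       samplerCfg = SamplerConfig(),
                       normSpec = ctWindowSpec(), targetSpacing = NULL,
                       resampleMethod = "nearest", checkpointDir = NULL,
                       verbose = FALSE) {
  stopifnot(length(trainCases) >= 1)
  if (any(samplerCfg@patchSize %% specDivisor(netSpec) != 0))
    stop("patchSize incompatible with the network's down-sampling chain")
  set.seed(trainCfg@seed)
  tr <- lapply(trainCases, prepCase, targetSpacing, normSpec, resampleMethod)
  va <- lapply(valCases, prepCase, targetSpacing, normSpec, resampleMethod)

  model <- buildVBNet(netSpec, seed = trainCfg@seed)
  state <- adamInit(model$params)

  # fixed validation patches (mask-centred so the structures are visible)
  valSampler <- SamplerConfig("mask", samplerCfg@patchSize,
                              samplerCfg@batchSize,
                              samplerCfg@foregroundThreshold)
  valPatches <- unlist(lapply(va, function(cs) {
    centers <- samplePatchCenters(cs$image, cs$label, valSampler,
                                  valSampler@batchSize)
    lapply(seq_len(nrow(centers)), function(i)
      extractPatch(cs$image, cs$label, centers[i, ], samplerCfg@patchSize))
  }), recursive = FALSE)

  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric(), val_dice = numeric(),
                    lr = numeric())
  best <- Inf; bestEpoch <- 0L; since <- 0L; bestParams <- model$params
  for (epoch in seq_len(trainCfg@epochs)) {
    lr <- trainCfg@lrInitial *
      trainCfg@lrFactor^((epoch - 1) %/% trainCfg@lrInterval)
    epochLoss <- 0; nBatches <- 0L
    for (cs in tr) {
      for (b in seq_len(trainCfg@batchesPerCase)) {
        batch <- drawBatch(cs, samplerCfg, trainCfg@augmentation)
        acc <- NULL; bl <- 0
        for (pt in batch) {
          fw <- vbnetForward(model, pt$x, withCache = TRUE)
          lg <- batchLossGrad(fw$scores, pt$y, lossCfg)
          if (!is.finite(lg$loss))
            stop("training diverged: non-finite loss at epoch ", epoch)
          bl <- bl + lg$loss / length(batch)
          gs <- vbnetBackward(model, fw$cache, lg$gscores)
          acc <- if (is.null(acc)) gs
                 else Map(function(a, b) a + b, acc, gs)
        }
        acc <- lapply(acc, function(g) g / length(batch))
        st <- adamStep(model$params, acc, state, lr, trainCfg@beta1,
                       trainCfg@beta2, trainCfg@weightDecay)
        model$params <- st$params; state <- st$state
        epochLoss <- epochLoss + bl; nBatches <- nBatches + 1L
      }
    }
    # validation at epoch end
    vl <- 0; vd <- 0
    for (pt in valPatches) {
      fw <- vbnetForward(model, pt$x)
      lg <- batchLossGrad(fw$scores, pt$y, lossCfg, withGrad = FALSE)
      vl <- vl + lg$loss / length(valPatches)
      hard <- argmaxClasses(lg$probs)
      vd <- vd + diceCoefficient(hard > 0, pt$y > 0) / length(valPatches)
    }
    log <- rbind(log, data.frame(epoch = epoch,
                                 train_loss = epochLoss / nBatches,
                                 val_loss = vl, val_dice = vd, lr = lr))
    if (verbose)
      message(sprintf("epoch %d: train %.4f val %.4f dice %.3f",
                      epoch, epochLoss / nBatches, vl, vd))
    if (vl < best - 1e-6) {
      best <- vl; bestEpoch <- epoch; since <- 0L
      bestParams <- model$params
    } else since <- since + 1L
    if (since >= trainCfg@patienceEpochs) break
  }
  model$params <- bestParams
  if (!is.null(checkpointDir))
    saveCheckpoint(model, checkpointDir,
                   meta = list(normalization = normSpecMeta(normSpec),
                               targetSpacing = targetSpacing,
                               resampleMethod = resampleMethod,
                               bestEpoch = bestEpoch))
  list(model = model, log = log, stopEpoch = nrow(log), bestEpoch = bestEpoch)
}

normSpecMeta <- function(ns) {
  list(mode = ns@mode, windowLevel = ns@windowLevel,
       windowWidth = ns@windowWidth, lowerPct = ns@lowerPct,
       upperPct = ns@upperPct)
}

normSpecFromMeta <- function(m) {
  if (is.null(m)) return(ctWindowSpec())
  new("NormalizationSpec", mode = m$mode, windowLevel = m$windowLevel,
      windowWidth = m$windowWidth, lowerPct = m$lowerPct,
      upperPct = m$upperPct)
}
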