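# Training objectives: 3D Dice, per-slice 2D Dice with adaptive weights,
# the combined multi-dimensional adaptive loss, boundary Dice and focal
# loss. Every loss has a companion *Grad function with the exact analytic
# gradient in the prediction; the training loop consumes probabilities, so
# gradients are in probability space.
#
# All Dice forms are smoothed: eps is added to numerator and denominator,
# which makes empty-vs-empty slices contribute 0 rather than NaN.

checkPredTarget <- function(pred, target) {
  if (!identical(dim2(pred), dim2(target)))
    stop("pred and target shapes differ")
  if (any(pred < -1e-9) || any(pred > 1 + 1e-9))
    stop("pred must be voxelwise probabilities in [0, 1]")
}

# dim() that treats plain vectors as 1D
dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

# smoothed soft Dice coefficient
softDice <- function(pred, target, smoothEps) {
  (2 * sum(pred * target) + smoothEps) / (sum(pred) + sum(target) + smoothEps)
}

#' 3D soft Dice loss
#'
#' `1 - (2 sum(p t) + eps) / (sum(p) + sum(t) + eps)`, differentiable in the
#' prediction.
#'
#' @param pred per-voxel foreground probabilities in `[0, 1]`.
#' @param target binary ground-truth grid of the same shape.
#' @param smoothEps smoothing constant added to numerator and denominator.
#' @return Scalar loss in `[0, 1]`.
#' @export
diceLoss3D <- function(pred, target, smoothEps = 1e-5) {
  checkPredTarget(pred, target)
  1 - softDice(pred, target, smoothEps)
}

#' @rdname diceLoss3D
#' @return `diceLoss3DGrad`: array of the same shape, the exact gradient of
#'   the loss in `pred`.
#' @export
diceLoss3DGrad <- function(pred, target, smoothEps = 1e-5) {
  checkPredTarget(pred, target)
  N <- 2 * sum(pred * target) + smoothEps
  D <- sum(pred) + sum(target) + smoothEps
  -(2 * target * D - N) / D^2
}

#' 2D soft Dice loss of a single slice
#'
#' Identical to [diceLoss3D()] restricted to one 2D slice; by smoothing, an
#' empty prediction against an empty target scores 0.
#'
#' @param predSlice,targetSlice 2D slice arrays.
#' @inheritParams diceLoss3D
#' @export
diceLoss2DSlice <- function(predSlice, targetSlice, smoothEps = 1e-5) {
  checkPredTarget(predSlice, targetSlice)
  1 - softDice(predSlice, targetSlice, smoothEps)
}

#' Adaptive weight of a 2D slice
#'
#' `1 - d^2` where `d` is the slice's smoothed Dice coefficient of the
#' current prediction: 0 for perfectly segmented slices, 1 for fully failed
#' ones, monotone decreasing in `d`. Used to focus the 2D loss terms on
#' poorly segmented slices (typically the superior/inferior boundary
#' slices of a target volume).
#'
#' @inheritParams diceLoss2DSlice
#' @return Scalar weight in `[0, 1]`.
#' @export
adaptiveSliceWeight <- function(predSlice, targetSlice, smoothEps = 1e-5) {
  checkPredTarget(predSlice, targetSlice)
  1 - softDice(predSlice, targetSlice, smoothEps)^2
}

sliceIndex <- function(x, axis, i) {
  switch(axis, x[i, , ], x[, i, ], x[, , i])
}

#' Multi-dimensional adaptive Dice loss
#'
#' `lambda1 * loss3D + lambda2 * sum_i w_i * loss2D_i`, the sum running
#' over all slices along `cfg@sliceAxis` and `w_i` being the adaptive
#' weight of slice i ([adaptiveSliceWeight()]). The weights are treated as
#' constants of the current prediction (no gradient flows through them),
#' so each step minimizes a convex combination of slice losses; pass
#' `sliceWeights` to evaluate the loss at externally fixed weights.
#'
#' @inheritParams diceLoss3D
#' @param cfg a [LossConfig-class].
#' @param sliceWeights optional fixed per-slice weights; default recomputes
#'   them from `pred`.
#' @return Scalar loss >= 0.
#' @export
adaptiveLoss <- function(pred, target, cfg = new("LossConfig"),
                         sliceWeights = NULL) {
  checkPredTarget(pred, target)
  ax <- cfg@sliceAxis
  n <- dim(pred)[ax]
  l3 <- diceLoss3D(pred, target, cfg@smoothEps)
  terms <- vapply(seq_len(n), function(i) {
    ps <- sliceIndex(pred, ax, i); ts <- sliceIndex(target, ax, i)
    w <- if (is.null(sliceWeights)) adaptiveSliceWeight(ps, ts, cfg@smoothEps)
         else sliceWeights[i]
    w * diceLoss2DSlice(ps, ts, cfg@smoothEps)
  }, numeric(1))
  s2 <- if (cfg@averageSlices) mean(terms) else sum(terms)
  cfg@lambda1 * l3 + cfg@lambda2 * s2
}

#' @rdname adaptiveLoss
#' @return `adaptiveLossGrad`: gradient array of the same shape as `pred`,
#'   with the slice weights frozen at their current (or supplied) values.
#' @export
adaptiveLossGrad <- function(pred, target, cfg = new("LossConfig"),
                             sliceWeights = NULL) {
  checkPredTarget(pred, target)
  ax <- cfg@sliceAxis
  n <- dim(pred)[ax]
  g <- cfg@lambda1 * diceLoss3DGrad(pred, target, cfg@smoothEps)
  denom <- if (cfg@averageSlices) n else 1
  for (i in seq_len(n)) {
    ps <- sliceIndex(pred, ax, i); ts <- sliceIndex(target, ax, i)
    w <- if (is.null(sliceWeights)) adaptiveSliceWeight(ps, ts, cfg@smoothEps)
         else sliceWeights[i]
    gi <- cfg@lambda2 * w / denom * diceLoss3DGrad(ps, ts, cfg@smoothEps)
    if (ax == 1L) g[i, , ] <- g[i, , ] + gi
    else if (ax == 2L) g[, i, ] <- g[, i, ] + gi
    else g[, , i] <- g[, , i] + gi
  }
  g
}

# ---- morphology helpers ----------------------------------------------------

shiftArray <- function(a, d, fill = 0) {
  dm <- dim(a)
  out <- array(fill, dm)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    if (d[ax] >= 0) {
      if (d[ax] >= dm[ax]) return(out)
      src[[ax]] <- 1:(dm[ax] - d[ax]); dst[[ax]] <- (1 + d[ax]):dm[ax]
    } else {
      if (-d[ax] >= dm[ax]) return(out)
      src[[ax]] <- (1 - d[ax]):dm[ax]; dst[[ax]] <- 1:(dm[ax] + d[ax])
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# one 26-neighbourhood (3x3x3 box) dilation step, iterated `width` times
binaryDilate <- function(a, width = 1L) {
  a <- a != 0
  for (w in seq_len(width)) {
    acc <- a
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      acc <- acc | shiftArray(a, c(dx, dy, dz), FALSE)
    }
    a <- acc
  }
  a
}

# erosion with the outside treated as background
binaryErode <- function(a, width = 1L) !binaryDilate(!(a != 0), width)

# boundary band of a binary target: dilation minus erosion
boundaryBand <- function(target, width) {
  binaryDilate(target, width) & !binaryErode(target, width)
}

#' Boundary Dice loss
#'
#' Dice loss restricted to the morphological boundary band of the target
#' (target dilated minus eroded by `cfg@boundaryWidthVox`, 26-neighbourhood
#' box element): prediction and target are masked to the band and the
#' smoothed Dice loss is evaluated there. A target with no boundary (all
#' background or all foreground) yields 0 with a warning.
#'
#' @inheritParams adaptiveLoss
#' @export
boundaryDiceLoss <- function(pred, target, cfg = new("LossConfig")) {
  checkPredTarget(pred, target)
  band <- boundaryBand(target, cfg@boundaryWidthVox)
  if (!any(band)) {
    warning("target has no boundary (all background or all foreground)")
    return(0)
  }
  diceLoss3D(pred * band, target * band, cfg@smoothEps)
}

#' @rdname boundaryDiceLoss
#' @export
boundaryDiceLossGrad <- function(pred, target, cfg = new("LossConfig")) {
  checkPredTarget(pred, target)
  band <- boundaryBand(target, cfg@boundaryWidthVox)
  if (!any(band)) return(array(0, dim(pred)))
  band * diceLoss3DGrad(pred * band, target * band, cfg@smoothEps)
}

#' Focal loss
#'
#' Mean of `-alpha * (1 - p_t)^gamma * log(p_t)` with
#' `p_t = p` on foreground and `1 - p` on background; probabilities are
#' clamped to `[eps, 1-eps]`. At `gamma = 0`, `alpha = 1` this is the mean
#' binary cross-entropy.
#'
#' @inheritParams diceLoss3D
#' @param gamma focusing exponent >= 0.
#' @param alpha class weight > 0.
#' @param eps clamping constant.
#' @export
focalLoss <- function(pred, target, gamma = 2, alpha = 1, eps = 1e-7) {
  checkPredTarget(pred, target)
  stopifnot(gamma >= 0)
  pt <- ifelse(target > 0, pred, 1 - pred)
  pt <- pmin(pmax(pt, eps), 1 - eps)
  mean(-alpha * (1 - pt)^gamma * log(pt))
}

#' @rdname focalLoss
#' @export
focalLossGrad <- function(pred, target, gamma = 2, alpha = 1, eps = 1e-7) {
  checkPredTarget(pred, target)
  pt <- ifelse(target > 0, pred, 1 - pred)
  pt <- pmin(pmax(pt, eps), 1 - eps)
  focusTerm <- if (gamma == 0) 0 else -gamma * (1 - pt)^(gamma - 1) * log(pt)
  dl_dpt <- -alpha * (focusTerm + (1 - pt)^gamma / pt)
  sgn <- ifelse(target > 0, 1, -1)
  g <- dl_dpt * sgn / length(pred)
  if (!is.null(dim(pred))) dim(g) <- dim(pred)
  g
}
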