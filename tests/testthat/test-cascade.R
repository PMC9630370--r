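# Cascade inference: sliding windows, localization, fine segmentation,
# attention maps, post-processing, and the composed two-stage run.

test_that("sliding-window tiling covers every voxel as the arithmetic says", {
  # closed-form check of start offsets for n=20, p=8, overlap 0.5
  starts <- vbcascade:::windowStarts(20L, 8L, 0.5)
  expect_equal(starts, c(0L, 4L, 8L, 12L))
  # coverage counts from the starts reproduce an explicit tally
  cover <- integer(20)
  for (s in starts) cover[(s + 1):(s + 8)] <- cover[(s + 1):(s + 8)] + 1L
  expect_true(all(cover >= 1))
  expect_equal(sum(cover), length(starts) * 8)
  # overlap 0 tiles without gaps and the last window is clamped
  s0 <- vbcascade:::windowStarts(20L, 8L, 0)
  expect_equal(s0, c(0L, 8L, 12L))
})

test_that("sliding-window prediction normalizes and handles small images", {
  m <- buildVBNet(NetworkSpec(levels = 1, baseChannels = 2), seed = 2)
  # image smaller than one patch: single padded window, cropped back
  x <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
  p <- slidingWindowPredict(x, m, patchSize = 8)
  expect_equal(dim(p), c(6, 5, 4, 2))
  expect_lt(max(abs(apply(p, 1:3, sum) - 1)), 1e-6)
  # constant-output dummy model: overlap 0 and 0.5 average equal values
  cm <- constantModel(c(0.3, 1.1))
  xc <- array(rnorm(16^3), c(16, 16, 16))
  p0 <- slidingWindowPredict(xc, cm, 8, 0)
  p5 <- slidingWindowPredict(xc, cm, 8, 0.5)
  expect_equal(p0, p5, tolerance = 1e-12)
  expect_equal(p0[1, 1, 1, 2], exp(1.1) / (exp(0.3) + exp(1.1)),
               tolerance = 1e-9)
  # channel mismatch is caught
  m3 <- buildVBNet(NetworkSpec(inChannels = 3, levels = 1, baseChannels = 2))
  expect_error(slidingWindowPredict(x, m3, 8), "channels")
})

test_that("coarse localization finds the organ box within one coarse voxel", {
  fix <- tinyCascadeFixture()
  cc <- tinyCascadeConfig()
  img <- fix$testCase$image
  lab <- fix$testCase$label
  box <- coarseLocalize(img, fix$coarse, cc, patchSize = 8)
  truth <- boundingBoxOf(lab, 1)
  # with the 6 mm margin the box must contain the true extent, and the
  # tight faces should be within one coarse voxel + margin of the truth
  expect_true(all(boxLo(box) <= boxLo(truth)))
  expect_true(all(boxHi(box) >= boxHi(truth)))
  slack <- 4 / spacing(img) + ceiling(cc@bboxMarginMm / spacing(img))
  expect_true(all(boxLo(truth) - boxLo(box) <= slack))
  expect_true(all(boxHi(box) - boxHi(truth) <= slack))
  # margin monotonicity: larger margin contains the smaller box
  cc0 <- tinyCascadeConfig(); cc0@bboxMarginMm <- c(0, 0, 0)
  cc10 <- tinyCascadeConfig(); cc10@bboxMarginMm <- c(10, 10, 10)
  b0 <- coarseLocalize(img, fix$coarse, cc0, patchSize = 8)
  b10 <- coarseLocalize(img, fix$coarse, cc10, patchSize = 8)
  expect_true(all(boxLo(b10) <= boxLo(b0)))
  expect_true(all(boxHi(b10) >= boxHi(b0)))
})

test_that("coarse detection failure falls back or errors as configured", {
  # a model that always votes background can never localize the label
  bg <- constantModel(c(1, 0))
  img <- Volume(array(rnorm(48^3, 40, 10), c(48, 48, 48)), spacing = 1)
  cc <- tinyCascadeConfig()
  expect_warning(box <- coarseLocalize(img, bg, cc, patchSize = 8),
                 "falling back")
  expect_equal(boxLo(box), c(0L, 0L, 0L))
  expect_equal(boxHi(box), c(48L, 48L, 48L))
  ccs <- cc; ccs@strictCoarse <- TRUE
  expect_error(coarseLocalize(img, bg, ccs, patchSize = 8),
               "coarse detection failure")
})

test_that("fine segmentation never predicts outside the box", {
  fix <- tinyCascadeFixture()
  cc <- tinyCascadeConfig()
  img <- fix$testCase$image
  box <- BoundingBox(c(10, 8, 12), c(34, 32, 36))
  seg <- fineSegment(img, box, fix$fine, cc, patchSize = 16)
  expect_equal(dim(seg), dim(img))
  outside <- seg@data
  outside[(boxLo(box)[1] + 1):boxHi(box)[1],
          (boxLo(box)[2] + 1):boxHi(box)[2],
          (boxLo(box)[3] + 1):boxHi(box)[3]] <- 0
  expect_equal(sum(outside), 0)
  # channel mismatch fails before any compute
  expect_error(fineSegment(img, box, fix$fine, cc,
                           attention = list(array(0, c(24, 24, 24)))),
               "channels")
})

test_that("OAR attention is the resampled union of the masks", {
  img <- Volume(array(0, c(24, 24, 24)), spacing = 2)
  cc <- CascadeConfig(coarseSpacing = 4, fineSpacing = 2)
  box <- BoundingBox(c(4, 4, 4), c(16, 16, 16))
  # no OARs -> all zero
  expect_true(all(makeOarAttention(list(), box, img, cc) == 0))
  # one OAR filling the box -> all one
  full <- array(0, c(24, 24, 24)); full[5:16, 5:16, 5:16] <- 1
  att <- makeOarAttention(list(LabelMask(full, 2)), box, img, cc)
  expect_equal(dim(att), c(12, 12, 12))
  expect_true(all(att == 1))
  # two disjoint OARs: voxel count adds
  a <- array(0, c(24, 24, 24)); a[5:7, 5:7, 5:7] <- 1
  b <- array(0, c(24, 24, 24)); b[12:14, 12:14, 12:14] <- 1
  attA <- makeOarAttention(list(LabelMask(a, 2)), box, img, cc)
  attB <- makeOarAttention(list(LabelMask(b, 2)), box, img, cc)
  attAB <- makeOarAttention(list(LabelMask(a, 2), LabelMask(b, 2)), box, img,
                            cc)
  expect_equal(sum(attAB), sum(attA) + sum(attB))
  expect_true(all(attAB %in% c(0, 1)))
})

test_that("boundary attention encodes the superior-inferior extent", {
  img <- Volume(array(0, c(40, 40, 40)), spacing = 1)
  cc <- CascadeConfig(coarseSpacing = 4, fineSpacing = 1)
  box <- BoundingBox(c(0, 0, 0), c(40, 40, 40))
  # coarse mask spanning the whole crop -> all ones
  cm <- LabelMask(array(1, c(10, 10, 10)), spacing = 4)
  expect_true(all(makeBoundaryAttention(box, cm, img, cc) == 1))
  # occupied coarse slices 3..5 (0-based 2..4) -> physical band
  # [8 mm, 20 mm); the map is constant within each axial slice
  cm2d <- array(0, c(10, 10, 10)); cm2d[, , 3:5] <- 1
  att <- makeBoundaryAttention(box, LabelMask(cm2d, 4), img, cc)
  perSlice <- apply(att, 3, function(s) length(unique(as.vector(s))))
  expect_true(all(perSlice == 1))
  on <- which(apply(att, 3, max) == 1)
  expect_equal(min(on), 9)   # 8 mm -> 0-based slice 8 -> 1-based 9
  expect_equal(max(on), 20)  # 19 mm, last slice below 20 mm
  expect_error(makeBoundaryAttention(box, LabelMask(cm2d * 0, 4), img, cc),
               "empty coarse target")
})

test_that("post-processing matches the flood-fill oracle and is idempotent", {
  cfg <- CascadeConfig(keepLargestCC = TRUE)
  # components of size 100 and 5: only the large one survives
  m <- array(0, c(12, 12, 12))
  m[2:6, 2:6, 2:5] <- 1          # 100 voxels
  m[10:11, 10:11, 10] <- 1       # 4 voxels (diagonal-disjoint from above)
  pp <- postProcess(LabelMask(m), cfg)
  expect_equal(sum(pp@data), 100)
  # single component: unchanged
  single <- LabelMask(array(as.numeric(randomBlobMask(c(8, 8, 8), 1)),
                            c(8, 8, 8)))
  expect_identical(postProcess(single, cfg)@data, single@data)
  # random multi-blob masks against the oracle, both modes
  set.seed(47)
  for (i in 1:8) {
    d <- sample(6:20, 3, TRUE)
    mm <- randomBlobMask(d, nBlobs = sample(2:4, 1))
    lab <- oComponents(mm)
    sizes <- tabulate(lab[lab > 0])
    keepCfg <- CascadeConfig(keepLargestCC = TRUE)
    got <- postProcess(LabelMask(mm * 1), keepCfg)
    keep <- which(sizes == max(sizes))[1]
    expect_identical(got@data != 0, lab == keep)
    rmCfg <- CascadeConfig(keepLargestCC = FALSE, minCCVoxels = 10L)
    got2 <- postProcess(LabelMask(mm * 1), rmCfg)
    surviving <- which(sizes >= 10)
    expect_identical(got2@data != 0, array(lab %in% surviving, d))
    # idempotence and the never-add guarantee
    expect_identical(postProcess(got, keepCfg)@data, got@data)
    expect_true(all(got@data[mm == 0] == 0))
  }
  # empty input passes through
  e <- LabelMask(array(0, c(4, 4, 4)))
  expect_identical(postProcess(e, cfg)@data, e@data)
})

test_that("the composed cascade recovers held-out phantom organs", {
  fix <- tinyCascadeFixture()
  cc <- tinyCascadeConfig()
  res <- runCascade(fix$testCase$image, fix$coarse, fix$fine, cc,
                    coarsePatchSize = 8, finePatchSize = 16)
  dice <- diceCoefficient(res$mask, fix$testCase$label)
  expect_gt(dice, 0.95)
  # structural guarantee: nothing outside the box
  out <- res$mask@data
  lo <- res$report$box$lo; hi <- res$report$box$hi
  out[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2], (lo[3] + 1):hi[3]] <- 0
  expect_equal(sum(out), 0)
  expect_named(res$report$seconds, c("coarse", "fine", "postprocess"))
  expect_equal(res$report$voxels[["predicted"]], sum(res$mask@data == 1))
  # attention configuration inconsistent with the model fails early
  ccAtt <- tinyCascadeConfig(); ccAtt@useBoundaryMap <- TRUE
  expect_error(runCascade(fix$testCase$image, fix$coarse, fix$fine, ccAtt,
                          coarsePatchSize = 8, finePatchSize = 16),
               "configuration error")
})

test_that("an attention-channel fine model trains and runs in the cascade", {
  fix <- tinyCascadeFixture()
  # two-channel fine model: raw image + boundary prior. Train briefly on
  # patches whose second channel is the true slice-extent indicator.
  cases <- lapply(fix$cases[1:4], function(cs) list(
    image = readVolume(file.path(cs, "image.nii.gz")),
    label = readVolume(file.path(cs, "label.nii.gz"), label = TRUE)))
  cc <- tinyCascadeConfig(); cc@useBoundaryMap <- TRUE
  fine2 <- buildVBNet(NetworkSpec(inChannels = 2, levels = 2,
                                  baseChannels = 4), seed = 9)
  st <- vbcascade:::adamInit(fine2$params)
  lossCfg <- LossConfig(components = c("dice3d", "adaptive2d"))
  set.seed(11)
  for (it in 1:140) {
    cs <- cases[[(it %% 4) + 1]]
    img <- normalizeIntensity(cs$image)
    ctr <- samplePatchCenters(img, cs$label,
                              SamplerConfig("mask", 16, 2), 1)
    p <- extractPatch(img, cs$label, ctr[1, ], c(16, 16, 16))
    zr <- range(which(apply(p$y > 0, 3, any)))
    bnd <- array(0, c(16, 16, 16))
    bnd[, , zr[1]:zr[2]] <- 1
    x2 <- array(c(p$x, bnd), c(16, 16, 16, 2))
    fw <- vbnetForward(fine2, x2, withCache = TRUE)
    lg <- vbcascade:::batchLossGrad(fw$scores, p$y, lossCfg)
    G <- vbnetBackward(fine2, fw$cache, lg$gscores)
    up <- vbcascade:::adamStep(fine2$params, G, st, 1e-2, 0.9, 0.999, 0)
    fine2$params <- up$params; st <- up$state
  }
  res <- runCascade(fix$testCase$image, fix$coarse, fine2, cc,
                    coarsePatchSize = 8, finePatchSize = 16)
  expect_gt(diceCoefficient(res$mask, fix$testCase$label), 0.8)
})
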