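# Patch samplers, augmentation, splits, the stopping rule and the
# reproducibility of the training loop.

prepSmall <- function(seed = 1, shape = 24, spacing = 2) {
  ph <- generatePhantom(smallPhantomSpec(shape = shape, spacing = spacing,
                                         seed = seed))
  list(image = normalizeIntensity(ph$image), label = ph$label)
}

test_that("mask sampling stays in the mask; degenerate ROI collapses", {
  cs <- prepSmall()
  cfg <- SamplerConfig("mask", patchSize = 8, batchSize = 2)
  set.seed(2)
  ctr <- samplePatchCenters(cs$image, cs$label, cfg, 50)
  expect_equal(nrow(ctr), 50L)
  expect_true(all(cs$label@data[ctr] > 0))
  # single-voxel mask: every centre equals that voxel
  m1 <- array(0, dim(cs$label@data)); m1[5, 6, 7] <- 1
  ctr1 <- samplePatchCenters(cs$image, LabelMask(m1, spacing(cs$label)),
                             cfg, 10)
  expect_true(all(ctr1[, 1] == 5 & ctr1[, 2] == 6 & ctr1[, 3] == 7))
  # empty candidate set names the scheme
  m0 <- LabelMask(array(0, dim(cs$label@data)), spacing(cs$label))
  expect_error(samplePatchCenters(cs$image, m0, cfg, 5), "mask sampling")
})

test_that("global sampling is uniform over the foreground (chi-square)", {
  cs <- prepSmall()
  cfg <- SamplerConfig("global", patchSize = 8, batchSize = 2,
                       foregroundThreshold = -0.9)
  set.seed(3)
  ctr <- samplePatchCenters(cs$image, cs$label, cfg, 10000)
  expect_true(all(cs$image@data[ctr] > -0.9))
  # octant counts vs expected proportional occupancy
  d <- dim(cs$image@data)
  half <- d %/% 2
  oct <- function(idx) {
    1 + (idx[, 1] > half[1]) + 2 * (idx[, 2] > half[2]) +
      4 * (idx[, 3] > half[3])
  }
  fg <- which(cs$image@data > -0.9, arr.ind = TRUE)
  expected <- tabulate(oct(fg), 8) / nrow(fg)
  observed <- tabulate(oct(ctr), 8)
  pv <- stats::chisq.test(observed, p = expected)$p.value
  expect_gt(pv, 0.01)
})

test_that("patch extraction pads out-of-grid regions as contracted", {
  cs <- prepSmall()
  d <- dim(cs$image@data)
  # interior patch: no padded voxels
  p <- extractPatch(cs$image, cs$label, d %/% 2, c(8, 8, 8))
  expect_equal(dim(p$x), c(8, 8, 8))
  expect_true(all(p$x > -1))  # body/organ intensities, no pad
  # corner patch: padded fraction matches the closed-form overlap.
  # use a constant image so pad voxels (-1) are unambiguous
  flat <- Volume(array(0.5, d), spacing(cs$image))
  pc <- extractPatch(flat, cs$label, c(1, 1, 1), c(8, 8, 8))
  # start = 1 - 4 = -3, so 4 in-grid voxels per axis
  inGrid <- prod(pmin(c(1, 1, 1) - 4 + 7, d) - pmax(c(1, 1, 1) - 4, 1) + 1)
  expect_equal(sum(pc$x == -1), 512 - inGrid)
  expect_equal(sum(pc$x == 0.5), inGrid)
  # label patch values are a subset of mask values plus padding 0
  expect_true(all(unique(as.vector(pc$y)) %in%
                    c(0, unique(as.vector(cs$label@data)))))
})

test_that("augmentation is identity when empty and involutive under flips", {
  cs <- prepSmall()
  p <- extractPatch(cs$image, cs$label, c(12, 12, 12), c(8, 8, 8))
  a0 <- augmentPatch(p$x, p$y, character())
  expect_identical(a0$x, p$x)
  expect_identical(a0$y, p$y)
  # replaying the same RNG state flips the same axes twice -> original
  set.seed(17)
  a1 <- augmentPatch(p$x, p$y, "flip")
  set.seed(17)
  a2 <- augmentPatch(a1$x, a1$y, "flip")
  expect_identical(a2$x, p$x)
  expect_identical(a2$y, p$y)
})

test_that("rotation moves a blob centroid as predicted by the angle", {
  # off-centre blob in a 17^3 patch (odd side: voxel-exact centre)
  x <- array(-1, c(17, 17, 17))
  y <- array(0, c(17, 17, 17))
  y[12:14, 8:10, 8:10] <- 1
  x[y > 0] <- 1
  set.seed(23)
  out <- augmentPatch(x, y, "rotate")
  set.seed(23)
  theta <- runif(1, -10, 10) * pi / 180
  ctr <- (dim(y) - 1) / 2
  c0 <- colMeans(which(y > 0, arr.ind = TRUE)) - 1 - ctr
  pred <- c(cos(theta) * c0[1] - sin(theta) * c0[2],
            sin(theta) * c0[1] + cos(theta) * c0[2], c0[3]) + ctr + 1
  got <- colMeans(which(out$y > 0, arr.ind = TRUE))
  expect_lt(max(abs(got - pred)), 1)
})

test_that("train/val splits are exhaustive, disjoint and seeded", {
  cases <- as.list(letters[1:10])
  s <- splitTrainVal(cases, 0.10, seed = 3)
  expect_length(s$val, 1)
  expect_length(s$train, 9)
  expect_setequal(c(unlist(s$train), unlist(s$val)), letters[1:10])
  expect_length(intersect(unlist(s$train), unlist(s$val)), 0)
  s2 <- splitTrainVal(cases, 0.10, seed = 3)
  expect_identical(s, s2)
  expect_error(splitTrainVal(cases[1], 0.1), "at least 2")
})

test_that("the convergence rule stops after patience non-improving epochs", {
  r <- stoppingEpoch(c(1.0, 0.9, 0.9, 0.9, 0.9, 0.9, 0.9), patience = 5)
  expect_equal(r$stopEpoch, 7)
  expect_equal(r$bestEpoch, 2)
  expect_true(r$stopped)
  # strictly decreasing: runs to the end
  r2 <- stoppingEpoch(seq(1, 0.05, by = -0.05), patience = 5)
  expect_false(r2$stopped)
  expect_equal(r2$bestEpoch, r2$stopEpoch)
  # infinite patience never stops earlier than patience 5
  set.seed(5)
  for (i in 1:10) {
    losses <- cumsum(rnorm(20, 0, 0.1)) + 1
    a <- stoppingEpoch(losses, patience = 5)
    b <- stoppingEpoch(losses, patience = 1000)
    expect_gte(b$stopEpoch, a$stopEpoch)
    # tolerance: an improvement below 1e-6 does not count
    expect_true(stoppingEpoch(c(1, 1 - 1e-8, 1 - 2e-8), 2)$stopped)
  }
})

test_that("training runs are bit-reproducible with fixed seeds", {
  dir <- file.path(tempdir(), "ds_repro")
  unlink(dir, recursive = TRUE)
  generateDataset(4, smallPhantomSpec(shape = 24, spacing = 2), seed = 13,
                  outDir = dir)
  cases <- listCases(dir)
  run <- function() {
    trainModel(cases[1:3], cases[4],
               NetworkSpec(levels = 2, baseChannels = 2),
               LossConfig(components = "dice3d"),
               TrainConfig(epochs = 2, lrInitial = 1e-2, batchesPerCase = 1,
                           seed = 7, augmentation = c("flip", "noise")),
               SamplerConfig("mixed", patchSize = 8, batchSize = 2),
               targetSpacing = c(4, 4, 4))
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$log, f2$log)
  expect_identical(f1$model$params, f2$model$params)
  expect_equal(nrow(f1$log), 2)
  expect_true(all(is.finite(f1$log$val_loss)))
})

test_that("incompatible patch sizes are rejected before training", {
  cs <- prepSmall()
  expect_error(
    trainModel(list(cs), list(cs), NetworkSpec(levels = 2, baseChannels = 2),
               samplerCfg = SamplerConfig("mask", patchSize = 10,
                                          batchSize = 2)),
    "patchSize")
})
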