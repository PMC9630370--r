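# Lazily trained tiny cascade shared by the cascade tests: 48 mm phantoms
# at 1 mm, a coarse stage at 4 mm and a fine stage at 1 mm. Training is
# deliberately small (a few epochs at a desk-scale learning rate) -- the
# phantom task is separable by intensity, so these models converge to
# near-perfect Dice in seconds.

.tcEnv <- new.env(parent = emptyenv())

# degenerate model with all weights zeroed: its output is the constant
# out-block bias for any input, which makes window-averaging and
# detection-failure behaviour exactly predictable
constantModel <- function(scores = c(1, 0), inChannels = 1L) {
  m <- buildVBNet(NetworkSpec(inChannels = inChannels,
                              outClasses = length(scores),
                              levels = 1, baseChannels = 2), seed = 1)
  m$params <- lapply(m$params, function(p) p * 0)
  m$params$out.b <- as.numeric(scores)
  m
}

tinyCascadeConfig <- function() {
  CascadeConfig(coarseSpacing = 4, fineSpacing = 1, bboxMarginMm = 6,
                keepLargestCC = TRUE)
}

tinyCascadeFixture <- function() {
  if (!is.null(.tcEnv$fix)) return(.tcEnv$fix)
  dir <- file.path(tempdir(), "tc_fixture_ds")
  unlink(dir, recursive = TRUE)
  generateDataset(8, PhantomSpec(shape = 48, spacing = 1, noiseSd = 10),
                  seed = 31, outDir = dir)
  cases <- listCases(dir)
  coarse <- trainModel(
    cases[1:6], cases[7],
    NetworkSpec(levels = 2, baseChannels = 4),
    LossConfig(components = "dice3d"),
    TrainConfig(epochs = 10, lrInitial = 1e-2, batchesPerCase = 2, seed = 3),
    SamplerConfig("global", patchSize = 8, batchSize = 2),
    targetSpacing = c(4, 4, 4), resampleMethod = "nearest")
  fine <- trainModel(
    cases[1:6], cases[7],
    NetworkSpec(levels = 2, baseChannels = 4),
    LossConfig(components = c("dice3d", "adaptive2d")),
    TrainConfig(epochs = 8, lrInitial = 1e-2, batchesPerCase = 2, seed = 4),
    SamplerConfig("mask", patchSize = 16, batchSize = 2),
    targetSpacing = c(1, 1, 1), resampleMethod = "linear")
  testCase <- list(
    image = readVolume(file.path(cases[8], "image.nii.gz")),
    label = readVolume(file.path(cases[8], "label.nii.gz"), label = TRUE))
  .tcEnv$fix <- list(dir = dir, cases = cases, coarse = coarse$model,
                     fine = fine$model, testCase = testCase)
  .tcEnv$fix
}
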