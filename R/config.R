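# Run configuration mirroring the recommended two-stage setting, plus the
# command-line surface.
#
# One JSON file drives both stages (coarse/fine sections). Every field has
# a default equal to the recommended configuration; unknown keys are
# rejected with the offending key named. (YAML is not supported: no YAML
# parser is available in the dependency set, and JSON carries the same
# structure.)

#' Default run configuration
#'
#' Coarse stage: 5 mm spacing, nearest-neighbour resampling, global
#' sampling, Dice + boundary Dice. Fine stage: 1 mm spacing, linear
#' resampling, mask sampling, Dice + boundary Dice (adaptive 2D Dice
#' available for target volumes). Both: patch 96^3, batch 2, Adam at
#' 1e-4 with step schedule, 1000 epochs max, patience 5, 10 percent
#' validation.
#'
#' @return Nested list of class `RunConfig`.
#' @export
defaultRunConfig <- function() {
  stage <- function(spacing, interp, scheme, components) {
    list(
      spacing = spacing,
      interpolation = interp,
      network = list(inChannels = 1L, outClasses = 2L, levels = 3L,
                     baseChannels = 8L, bottlenecksPerBlock = 1L,
                     adaptiveInput = FALSE),
      sampler = list(scheme = scheme, patchSize = c(96L, 96L, 96L),
                     batchSize = 2L, foregroundThreshold = -0.9),
      loss = list(lambda1 = 0.7, lambda2 = 0.3, smoothEps = 1e-5,
                  boundaryWidthVox = 2L, sliceAxis = 3L,
                  components = components, averageSlices = FALSE,
                  focalGamma = 2, focalAlpha = 1),
      train = list(epochs = 1000L, lrInitial = 1e-4, lrFactor = 0.1,
                   lrInterval = 250L, weightDecay = 1e-4, beta1 = 0.9,
                   beta2 = 0.999, valFraction = 0.10, patienceEpochs = 5L,
                   batchesPerCase = 4L,
                   augmentation = c("rotate", "scale", "flip", "shift",
                                    "noise")))
  }
  structure(list(
    seed = 1L,
    outputDir = ".",
    normalization = list(mode = "ct_window", windowLevel = 40,
                         windowWidth = 400, lowerPct = 0.5, upperPct = 99.5),
    coarse = stage(c(5, 5, 5), "nearest", "global",
                   c("dice3d", "boundary_dice")),
    fine = stage(c(1, 1, 1), "linear", "mask",
                 c("dice3d", "boundary_dice")),
    cascade = list(bboxMarginMm = c(10, 10, 10), windowOverlap = 0,
                   keepLargestCC = TRUE, minCCVoxels = 27L,
                   useOarMap = FALSE, useBoundaryMap = FALSE,
                   strictCoarse = FALSE)
  ), class = "RunConfig")
}

mergeConfig <- function(defaults, user, path = "") {
  for (k in names(user)) {
    full <- if (path == "") k else paste0(path, ".", k)
    if (!k %in% names(defaults))
      stop("unknown configuration key: ", full)
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(user[[k]]))
        stop("configuration key ", full, " must be a section")
      defaults[[k]] <- mergeConfig(defaults[[k]], user[[k]], full)
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

# build (and thereby validate) the S4 objects of one stage
stageObjects <- function(cfg, stage) {
  s <- cfg[[stage]]
  n <- s$network
  list(
    spacing = as.numeric(s$spacing),
    interpolation = s$interpolation,
    netSpec = NetworkSpec(n$inChannels, n$outClasses, n$levels,
                          n$baseChannels, n$bottlenecksPerBlock,
                          isTRUE(n$adaptiveInput)),
    samplerCfg = SamplerConfig(s$sampler$scheme,
                               as.integer(s$sampler$patchSize),
                               s$sampler$batchSize,
                               s$sampler$foregroundThreshold),
    lossCfg = LossConfig(s$loss$lambda1, s$loss$lambda2, s$loss$smoothEps,
                         s$loss$boundaryWidthVox, s$loss$sliceAxis,
                         unlist(s$loss$components), isTRUE(s$loss$averageSlices),
                         s$loss$focalGamma, s$loss$focalAlpha),
    trainCfg = TrainConfig(s$train$epochs, s$train$lrInitial, s$train$lrFactor,
                           s$train$lrInterval, s$train$weightDecay,
                           s$train$beta1, s$train$beta2, s$train$valFraction,
                           s$train$patienceEpochs, s$train$batchesPerCase,
                           unlist(s$train$augmentation) %||% character(),
                           as.integer(cfg$seed)))
}

configNormSpec <- function(cfg) {
  n <- cfg$normalization
  new("NormalizationSpec", mode = n$mode, windowLevel = n$windowLevel,
      windowWidth = n$windowWidth, lowerPct = n$lowerPct,
      upperPct = n$upperPct)
}

configCascade <- function(cfg) {
  cc <- cfg$cascade
  CascadeConfig(as.numeric(cfg$coarse$spacing), as.numeric(cfg$fine$spacing),
                as.numeric(cc$bboxMarginMm), cc$windowOverlap,
                isTRUE(cc$keepLargestCC), cc$minCCVoxels,
                isTRUE(cc$useOarMap), isTRUE(cc$useBoundaryMap),
                isTRUE(cc$strictCoarse))
}

#' Load a run configuration from JSON
#'
#' Missing fields take their defaults; unknown keys and invalid values are
#' rejected with the key and constraint named. An empty file yields the
#' pure defaults.
#'
#' @param path path to a JSON configuration file.
#' @return Validated `RunConfig` list.
#' @export
loadConfig <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  user <- if (!nzchar(trimws(txt))) list() else
    jsonlite::fromJSON(txt, simplifyVector = TRUE)
  cfg <- mergeConfig(defaultRunConfig(), user)
  class(cfg) <- "RunConfig"
  # validation: constructing the S4 config objects runs their validity
  for (stage in c("coarse", "fine")) stageObjects(cfg, stage)
  configNormSpec(cfg)
  configCascade(cfg)
  cfg
}

#' Write a run configuration as JSON
#'
#' @param cfg a `RunConfig` list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
dumpConfig <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# CLI
# ---------------------------------------------------------------------------

logMsg <- function(...) {
  message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S "), sprintf(...))
}

cliUsage <- function() {
  message(paste(
    "usage: vbcascade <command> [options]",
    "commands:",
    "  phantom  --cases N --out DIR [--seed S] [--shape N] [--spacing MM] [--noise SD]",
    "  train    --data DIR --out CKPT --stage coarse|fine [--config FILE] [--seed S] [--epochs N]",
    "  infer    --image FILE --coarse CKPT --fine CKPT --out FILE [--config FILE] [--oar-masks DIR]",
    "  evaluate --pred DIR --truth DIR --out DIR",
    sep = "\n"))
}

parseArgs <- function(argv) {
  out <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i == length(argv) || startsWith(argv[i + 1], "--"))
      stop("option --", key, " needs a value")
    out[[key]] <- argv[i + 1]
    i <- i + 2L
  }
  out
}

cliRequire <- function(opts, keys) {
  miss <- setdiff(keys, names(opts))
  if (length(miss))
    stop("missing required option(s): ", paste0("--", miss, collapse = ", "))
}

cliPhantom <- function(opts) {
  cliRequire(opts, c("cases", "out"))
  seed <- as.integer(opts$seed %||% 1)
  shape <- as.integer(opts$shape %||% 64)
  spac <- as.numeric(opts$spacing %||% 1)
  noise <- as.numeric(opts$noise %||% 10)
  base <- PhantomSpec(shape = shape, spacing = spac, noiseSd = noise)
  logMsg("generating %s phantom cases into %s (seed %d)", opts$cases,
         opts$out, seed)
  generateDataset(as.integer(opts$cases), base, seed = seed,
                  outDir = opts$out)
  0L
}

cliTrain <- function(opts) {
  cliRequire(opts, c("data", "out", "stage"))
  if (!dir.exists(opts$data)) stop("data directory not found: ", opts$data)
  cfg <- if (!is.null(opts$config)) loadConfig(opts$config) else
    defaultRunConfig()
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  if (!is.null(opts$epochs))
    cfg[[opts$stage]]$train$epochs <- as.integer(opts$epochs)
  so <- stageObjects(cfg, opts$stage)
  cases <- listCases(opts$data)
  split <- splitTrainVal(cases, so$trainCfg@valFraction, cfg$seed)
  logMsg("training %s stage on %d cases (%d validation)", opts$stage,
         length(split$train), length(split$val))
  fit <- trainModel(split$train, split$val, so$netSpec, so$lossCfg,
                    so$trainCfg, so$samplerCfg, configNormSpec(cfg),
                    targetSpacing = so$spacing,
                    resampleMethod = so$interpolation,
                    checkpointDir = opts$out)
  write.csv(fit$log, file.path(opts$out, "training_log.csv"),
            row.names = FALSE)
  dumpConfig(cfg, file.path(opts$out, "effective_config.json"))
  logMsg("best epoch %d (val loss %.4f); checkpoint in %s", fit$bestEpoch,
         min(fit$log$val_loss), opts$out)
  0L
}

cliInfer <- function(opts) {
  cliRequire(opts, c("image", "coarse", "fine", "out"))
  cfg <- if (!is.null(opts$config)) loadConfig(opts$config) else
    defaultRunConfig()
  image <- readVolume(opts$image)
  coarseM <- loadCheckpoint(opts$coarse)
  fineM <- loadCheckpoint(opts$fine)
  cascadeCfg <- configCascade(cfg)
  oarMasks <- NULL
  if (!is.null(opts[["oar-masks"]])) {
    files <- list.files(opts[["oar-masks"]], pattern = "\\.nii(\\.gz)?$",
                        full.names = TRUE)
    oarMasks <- lapply(files, readVolume, label = TRUE)
  }
  cp <- as.integer(cfg$coarse$sampler$patchSize)
  fp <- as.integer(cfg$fine$sampler$patchSize)
  logMsg("running cascade on %s", opts$image)
  res <- runCascade(image, coarseM, fineM, cascadeCfg, oarMasks,
                    coarsePatchSize = cp, finePatchSize = fp)
  writeVolume(res$mask, opts$out)
  jsonlite::write_json(res$report, paste0(opts$out, ".report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logMsg("wrote %s (%d foreground voxels)", opts$out,
         sum(res$mask@data > 0))
  0L
}

cliEvaluate <- function(opts) {
  cliRequire(opts, c("pred", "truth", "out"))
  res <- evaluateCases(opts$pred, opts$truth, outDir = opts$out)
  if (length(res$unmatched))
    logMsg("unmatched cases: %s", paste(res$unmatched, collapse = ", "))
  logMsg("evaluated %d records; summaries in %s", nrow(res$records),
         opts$out)
  0L
}

#' Command-line entry point
#'
#' Subcommands: `phantom` (generate a synthetic dataset), `train` (train a
#' coarse or fine stage on a case directory), `infer` (run the cascade on
#' one image), `evaluate` (Dice tables for a prediction directory).
#' `--seed` overrides the config seed. Returns a non-zero status on any
#' error; usage errors print a synopsis.
#'
#' @param argv character vector of arguments (excluding the program name).
#' @return Integer exit status (0 on success).
#' @export
cliMain <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0L) { cliUsage(); return(1L) }
  cmd <- argv[1]
  tryCatch({
    opts <- parseArgs(argv[-1])
    switch(cmd,
      phantom = cliPhantom(opts),
      train = cliTrain(opts),
      infer = cliInfer(opts),
      evaluate = cliEvaluate(opts),
      { cliUsage(); stop("unknown command: ", cmd) })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
}
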