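# Segmentation evaluation: Dice coefficient, per-case tables, summaries.

#' Dice coefficient between two binary masks
#'
#' `2|P & T| / (|P| + |T|)`; defined as 1 when both masks are empty
#' (perfect agreement on absence) and 0 when exactly one is empty.
#' Symmetric in its arguments.
#'
#' @param pred,truth binary arrays (or [LabelMask-class]) of the same
#'   shape; non-zero counts as foreground.
#' @return Scalar in `[0, 1]`.
#' @export
diceCoefficient <- function(pred, truth) {
  if (is(pred, "Volume")) pred <- pred@data
  if (is(truth, "Volume")) truth <- truth@data
  if (!identical(dim2(pred), dim2(truth)))
    stop("pred and truth geometry mismatch")
  p <- pred != 0
  t <- truth != 0
  np <- sum(p); nt <- sum(t)
  if (np + nt == 0) return(1)
  2 * sum(p & t) / (np + nt)
}

# find (id, path) pairs: either case directories holding label.nii.gz /
# seg.nii.gz, or flat <id>.nii.gz files
findMaskFiles <- function(dir, preferred = c("seg.nii.gz", "label.nii.gz")) {
  subs <- list.dirs(dir, recursive = FALSE)
  out <- list()
  for (s in subs) {
    for (f in preferred) {
      p <- file.path(s, f)
      if (file.exists(p)) { out[[basename(s)]] <- p; break }
    }
  }
  flat <- list.files(dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  for (p in flat) {
    id <- sub("\\.nii(\\.gz)?$", "", basename(p))
    if (is.null(out[[id]])) out[[id]] <- p
  }
  out
}

#' Evaluate predicted masks against ground truth
#'
#' Matches cases by id between two directories (either flat
#' `<case>.nii.gz` files or `case_XXXX/` directories containing
#' `seg.nii.gz` / `label.nii.gz`), computes one record per (case, label)
#' with Dice and voxel counts, and per-label mean and SD. Unmatched cases
#' are listed, never silently dropped.
#'
#' @param predDir directory of predicted masks.
#' @param truthDir directory of ground-truth masks.
#' @param outDir if non-NULL, `records.csv` and `summary.csv` are written
#'   there.
#' @return list(records, summary, unmatched); `records` has columns case,
#'   label, dice, voxels_pred, voxels_true.
#' @export
evaluateCases <- function(predDir, truthDir, outDir = NULL) {
  preds <- findMaskFiles(predDir)
  truths <- findMaskFiles(truthDir, preferred = "label.nii.gz")
  ids <- sort(intersect(names(preds), names(truths)))
  unmatched <- sort(c(setdiff(names(preds), names(truths)),
                      setdiff(names(truths), names(preds))))
  rec <- list()
  for (id in ids) {
    pm <- readVolume(preds[[id]], label = TRUE)
    tm <- readVolume(truths[[id]], label = TRUE)
    labs <- setdiff(sort(unique(c(as.vector(pm@data), as.vector(tm@data)))), 0)
    if (length(labs) == 0L) labs <- 1
    for (k in labs) {
      rec[[length(rec) + 1L]] <- data.frame(
        case = id, label = k,
        dice = diceCoefficient(pm@data == k, tm@data == k),
        voxels_pred = sum(pm@data == k), voxels_true = sum(tm@data == k))
    }
  }
  records <- if (length(rec)) do.call(rbind, rec) else
    data.frame(case = character(), label = numeric(), dice = numeric(),
               voxels_pred = numeric(), voxels_true = numeric())
  summary <- do.call(rbind, lapply(split(records, records$label), function(g)
    data.frame(label = g$label[1], n = nrow(g), mean_dice = mean(g$dice),
               sd_dice = stats::sd(g$dice))))
  rownames(summary) <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(records, file.path(outDir, "records.csv"), row.names = FALSE)
    write.csv(summary, file.path(outDir, "summary.csv"), row.names = FALSE)
  }
  list(records = records, summary = summary, unmatched = unmatched)
}
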