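## Level-wise classification metrics, ROC/AUC and false-positives-per-scan
## reporting. The nodule class is the positive class throughout.

#' Confusion counts for binary nodule/non-nodule predictions
#'
#' @param labels,predictions equal-length vectors, either
#'   "nodule"/"non_nodule" character or 0/1 (1 = nodule).
#' @return Named list with integer \code{TP}, \code{FP}, \code{TN},
#'   \code{FN} (summing to the number of objects).
#' @export
confusionCounts <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels and predictions must have equal length")
  y <- labelsToInt(labels)
  p <- labelsToInt(predictions)
  list(TP = sum(y == 1L & p == 1L), FP = sum(y == 0L & p == 1L),
       TN = sum(y == 0L & p == 0L), FN = sum(y == 1L & p == 0L))
}

#' Accuracy, sensitivity, specificity and F1 from confusion counts
#'
#' Standard definitions: sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP), ACC = (TP+TN)/total, F1 = 2TP/(2TP+FP+FN) with nodule as
#' the positive class. A metric with a zero denominator is reported as NA
#' (undefined), never as 0. When both class denominators are nonzero, ACC
#' is the prevalence-weighted average of sensitivity and specificity and
#' hence lies between them.
#'
#' @param counts list with TP, FP, TN, FN (see
#'   \code{\link{confusionCounts}}).
#' @return Named list \code{acc}, \code{sens}, \code{spec}, \code{f1}.
#' @export
classificationMetrics <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  total <- tp + fp + tn + fn
  if (total == 0L) stop("no objects to evaluate")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  list(acc = (tp + tn) / total, sens = sens, spec = spec, f1 = f1)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the unique scores as thresholds (predict nodule when score >=
#' threshold) and integrates the ROC curve by the trapezoid rule, which
#' equals the Mann-Whitney statistic P(score_pos > score_neg) + 1/2
#' P(tie).
#'
#' @param labels binary labels (nodule positive).
#' @param scores continuous scores, higher = more nodule-like.
#' @return List with \code{curve} (data.frame threshold, fpr, tpr) and
#'   \code{auc} (NA with a warning if only one class is present).
#' @export
rocAuc <- function(labels, scores) {
  y <- labelsToInt(labels)
  stopifnot(length(y) == length(scores))
  nPos <- sum(y == 1L); nNeg <- sum(y == 0L)
  if (nPos == 0L || nNeg == 0L) {
    warning("single-class labels: AUC undefined")
    return(list(curve = data.frame(threshold = numeric(0), fpr = numeric(0),
                                   tpr = numeric(0)), auc = NA_real_))
  }
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(scores >= t & y == 1L) / nPos, numeric(1))
  fpr <- vapply(th, function(t) sum(scores >= t & y == 0L) / nNeg, numeric(1))
  curve <- data.frame(threshold = c(Inf, th), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  n <- nrow(curve)
  auc <- sum((curve$fpr[-1] - curve$fpr[-n]) *
             (curve$tpr[-1] + curve$tpr[-n]) / 2)
  # close the curve to (1, 1) in case of score ties at the minimum
  if (curve$fpr[n] < 1 || curve$tpr[n] < 1)
    auc <- auc + (1 - curve$fpr[n]) * (1 + curve$tpr[n]) / 2
  list(curve = curve, auc = auc)
}

#' False positives per scan
#'
#' Total volume-level false-positive calls divided by the number of
#' distinct scans in the evaluated set.
#'
#' @param scanIds scan identifier per evaluated object.
#' @param labels,predictions per-object labels and predicted labels.
#' @return Non-negative scalar.
#' @export
fpPerScan <- function(scanIds, labels, predictions) {
  stopifnot(length(scanIds) == length(labels),
            length(labels) == length(predictions))
  nScans <- length(unique(scanIds))
  if (nScans == 0L) stop("zero scans in the evaluated set")
  confusionCounts(labels, predictions)$FP / nScans
}

metricsRow <- function(level, perspective, labels, scores) {
  preds <- as.integer(scores >= 0.5)
  m <- classificationMetrics(confusionCounts(labels, preds))
  roc <- suppressWarnings(rocAuc(labels, scores))
  list(row = data.frame(level = level, perspective = perspective,
                        acc = m$acc, auc = roc$auc, f1 = m$f1,
                        sens = m$sens, spec = m$spec),
       curve = roc$curve)
}

#' Level-wise evaluation report for a hierarchical model
#'
#' Evaluates a trained hierarchy on test records at all three levels:
#' slice level (per perspective, individual slices with inherited VOI
#' labels as units), perspective level (per perspective, VOIs as units)
#' and volume level (VOIs as units), with ROC curves per row and the
#' volume-level false positives per scan.
#'
#' @param model a trained \linkS4class{HierarchicalModel}.
#' @param records test records (disjoint from training), each with
#'   \code{$stacks}, \code{$label} and \code{$scanId}.
#' @return An \linkS4class{EvaluationReport} (7 metric rows: 3 slice,
#'   3 perspective, 1 volume).
#' @export
levelReport <- function(model, records) {
  if (length(records) == 0L) stop("empty test set")
  labels <- vapply(records, function(r) r$label, character(1))
  scanIds <- vapply(records, function(r)
    if (is.null(r$scanId)) NA_character_ else r$scanId, character(1))
  preds <- lapply(records, function(r) predictHierarchy(model, r))

  rows <- list(); curves <- list()
  for (p in PERSPECTIVES) {
    sliceScores <- unlist(lapply(preds, function(pr)
      assemblePerspectiveFeatures(pr$sliceScores[[p]])))
    nSl <- vapply(preds, function(pr) nrow(pr$sliceScores[[p]]), integer(1))
    sliceLabels <- rep(labels, nSl)
    r <- metricsRow("slice", p, sliceLabels, sliceScores)
    rows <- c(rows, list(r$row)); curves[[paste0("slice_", p)]] <- r$curve
  }
  for (p in PERSPECTIVES) {
    pScores <- vapply(preds, function(pr) pr$perspectiveScores[[p]],
                      numeric(1))
    r <- metricsRow("perspective", p, labels, pScores)
    rows <- c(rows, list(r$row))
    curves[[paste0("perspective_", p)]] <- r$curve
  }
  vScores <- vapply(preds, function(pr) pr$volumeScore, numeric(1))
  r <- metricsRow("volume", "all", labels, vScores)
  rows <- c(rows, list(r$row)); curves[["volume"]] <- r$curve

  vPreds <- as.integer(vScores >= 0.5)
  fps <- if (all(is.na(scanIds))) NA_real_
         else fpPerScan(scanIds, labels, vPreds)
  new("EvaluationReport", metrics = do.call(rbind, rows), roc = curves,
      fpPerScan = fps, nScans = length(unique(scanIds[!is.na(scanIds)])),
      nObjects = length(records))
}

#' Write an evaluation report to CSV/JSON files
#'
#' Writes \code{metrics.csv} (columns level, perspective, acc, auc, f1,
#' sens, spec), one \code{roc_<name>.csv} per ROC curve and, if
#' \pkg{jsonlite} is available, \code{report.json}.
#'
#' @param report an \linkS4class{EvaluationReport}.
#' @param dir output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report@metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  for (nm in names(report@roc))
    utils::write.csv(report@roc[[nm]], file.path(dir, paste0("roc_", nm, ".csv")),
                     row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(metrics = report@metrics, fp_per_scan = report@fpPerScan,
           n_scans = report@nScans, n_objects = report@nObjects),
      file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
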