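# Precision-recall machinery: PR curves, AUPRC, precision at fixed recall,
# top F1, and recall-calibrated threshold selection.
#
# The decision rule everywhere is "predict active if score > alpha". The
# curve has one operating point per distinct score value (all items sharing
# a score enter or leave the positive set together); the lowest distinct
# score always yields the recall = 1 operating point. AUPRC uses
# right-continuous step integration (sum of precision times recall
# increments), not trapezoids, to avoid optimistic interpolation.

#' Precision-recall curve
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (1 = positive) of equal length.
#' @return A `pr_curve` tibble with columns `threshold` (distinct scores,
#'   descending), `tp`, `fp`, `precision`, `recall`; attributes `n_pos`,
#'   `n_neg`. At row i the positive set is every item with
#'   `score >= threshold[i]`.
#' @examples
#' pr_curve(c(0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 1))
#' @export
pr_curve <- function(scores, labels) {
  if (length(scores) != length(labels)) stopf("scores and labels differ in length")
  if (!all(labels %in% c(0, 1))) stopf("labels must be binary (0/1)")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L)
    stopf("need at least one positive and one negative label")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  ct <- cumsum(y); cf <- cumsum(1 - y)
  last <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie group
  tp <- ct[last]; fp <- cf[last]
  curve <- tibble::tibble(
    threshold = s[last],
    tp = as.integer(tp), fp = as.integer(fp),
    precision = tp / (tp + fp),
    recall = tp / n_pos
  )
  attr(curve, "n_pos") <- as.integer(n_pos)
  attr(curve, "n_neg") <- as.integer(n_neg)
  class(curve) <- c("pr_curve", class(curve))
  curve
}

#' Area under the precision-recall curve
#'
#' Right-continuous step integration over recall in `[0, 1]`:
#' `sum(precision_i * (recall_i - recall_(i-1)))` with `recall_0 = 0`.
#'
#' @param curve A [pr_curve()].
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(curve) {
  sum(curve$precision * diff(c(0, curve$recall)))
}

#' Precision at a fixed recall target
#'
#' The maximum precision over operating points whose recall meets the
#' target. Because the recall = 1 point always exists, the result is
#' defined for any target in `[0, 1]`. The default 0.95 reflects the
#' priority of settlement coverage over raw prediction correctness.
#'
#' @param curve A [pr_curve()].
#' @param target Recall target in `[0, 1]` (default 0.95).
#' @return Precision in `[0, 1]`.
#' @export
precision_at_recall <- function(curve, target = 0.95) {
  if (target < 0 || target > 1) stopf("`target` must be in [0, 1]")
  max(curve$precision[curve$recall >= target])
}

#' Top F1 score over a precision-recall curve
#' @param curve A [pr_curve()].
#' @return Maximum of `2pr / (p + r)` over operating points.
#' @export
best_f1 <- function(curve) {
  p <- curve$precision; r <- curve$recall
  f1 <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  max(f1)
}

#' Calibrate a decision threshold for a target recall
#'
#' Returns the largest threshold `alpha` such that the rule
#' `score > alpha` retains at least `ceiling(target * n_pos)` positives:
#' `alpha` sits just below the k-th largest positive score (at the midpoint
#' to the next lower distinct score, but no more than 1e-6 below, so the
#' operating point is as selective as the data allows).
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels of equal length.
#' @param target_recall Recall to retain among labeled positives
#'   (default 0.95, the deployment calibration used for region scans).
#' @return The threshold `alpha` (numeric scalar).
#' @export
calibrate_threshold <- function(scores, labels, target_recall = 0.95) {
  if (length(scores) != length(labels)) stopf("scores and labels differ in length")
  pos <- scores[labels == 1]
  if (length(pos) == 0L) stopf("no positive labels: cannot calibrate recall")
  if (target_recall < 0 || target_recall > 1) stopf("`target_recall` must be in [0, 1]")
  k <- ceiling(target_recall * length(pos))
  if (k == 0L) return(max(scores))
  s_k <- sort(pos, decreasing = TRUE)[k]
  lower <- unique(sort(scores[scores < s_k], decreasing = TRUE))
  gap <- if (length(lower)) s_k - lower[1] else 2e-6
  s_k - min(1e-6, gap / 2)
}

#' Full metrics report for a set of scored tiles
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels.
#' @param target_recall Recall target for [precision_at_recall()].
#' @return A `metrics_report` list: `auprc`, `precision_at_recall`,
#'   `target_recall`, `best_f1`, `n_pos`, `n_neg`.
#' @export
metrics_report <- function(scores, labels, target_recall = 0.95) {
  curve <- pr_curve(scores, labels)
  structure(
    list(auprc = auprc(curve),
         precision_at_recall = precision_at_recall(curve, target_recall),
         target_recall = target_recall,
         best_f1 = best_f1(curve),
         n_pos = attr(curve, "n_pos"),
         n_neg = attr(curve, "n_neg")),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> AUPRC=%.3f  precision@%.2f-recall=%.3f  top-F1=%.3f  (%d pos / %d neg)\n",
    x$auprc, x$target_recall, x$precision_at_recall, x$best_f1, x$n_pos, x$n_neg))
  invisible(x)
}

#' Write a metrics report to JSON
#' @param report A `metrics_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a PR curve to CSV
#' @param curve A [pr_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pr_csv <- function(curve, path) {
  utils::write.csv(curve[, c("threshold", "precision", "recall")], path,
                   row.names = FALSE)
  invisible(path)
}
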