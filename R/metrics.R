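# Classification metrics: sensitivity, specificity, their mean (UAR,
# unweighted average recall) and the two rank areas.

#' Construct a metric set
#'
#' UAR is always recomputed as `(sensitivity + specificity) / 2`; the
#' identity holds for every metric set ever constructed.
#'
#' @param sensitivity recall on the ASD class, in `[0, 1]`.
#' @param specificity recall on the NT class, in `[0, 1]`.
#' @param auc_roc,auc_pr rank areas in `[0, 1]` (may be `NA` when no
#'   scores are available).
#' @return An object of class `metric_set` with fields `sensitivity`,
#'   `specificity`, `uar`, `auc_roc`, `auc_pr`.
#' @examples
#' m <- metric_set(0.8939, 0.7536)
#' round(m$uar, 4)
#' @export
metric_set <- function(sensitivity, specificity, auc_roc = NA_real_,
                       auc_pr = NA_real_) {
  vals <- c(sensitivity, specificity, auc_roc, auc_pr)
  ok <- !is.na(vals)
  if (any(vals[ok] < 0 | vals[ok] > 1)) stop("metrics must lie in [0, 1]")
  uar <- (sensitivity + specificity) / 2
  stopifnot(identical(uar, (sensitivity + specificity) / 2))
  structure(
    list(sensitivity = sensitivity, specificity = specificity, uar = uar,
         auc_roc = auc_roc, auc_pr = auc_pr),
    class = "metric_set"
  )
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf(
    "sens %.4f  spec %.4f  UAR %.4f  AUC-ROC %.4f  AUC-PR %.4f\n",
    x$sensitivity, x$specificity, x$uar, x$auc_roc, x$auc_pr))
  invisible(x)
}

# ROC / PR points via rank integration; ties are grouped.
.rank_curves <- function(y, s) {
  ord <- order(s, decreasing = TRUE)
  ys <- y[ord]; ss <- s[ord]
  keep <- c(diff(ss) != 0, TRUE)
  tp <- cumsum(ys)[keep]
  fp <- cumsum(1 - ys)[keep]
  list(tp = tp, fp = fp, P = sum(y), N = sum(1 - y))
}

#' Area under the ROC curve (trapezoidal rank integration)
#'
#' @param y_true 0/1 (or ASD/NT) labels with both classes present.
#' @param y_score continuous scores, larger = more ASD-like.
#' @return AUC-ROC in `[0, 1]`; tied scores contribute 1/2.
#' @export
auc_roc <- function(y_true, y_score) {
  y <- label_to_binary(y_true)
  if (length(unique(y)) < 2) stop("rank metrics undefined for single-class y_true")
  cv <- .rank_curves(y, y_score)
  tpr <- c(0, cv$tp / cv$P)
  fpr <- c(0, cv$fp / cv$N)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Area under the precision-recall curve (trapezoidal rank integration)
#'
#' @inheritParams auc_roc
#' @return AUC-PR in `[0, 1]`.
#' @export
auc_pr <- function(y_true, y_score) {
  y <- label_to_binary(y_true)
  if (length(unique(y)) < 2) stop("rank metrics undefined for single-class y_true")
  cv <- .rank_curves(y, y_score)
  rec <- cv$tp / cv$P
  prec <- cv$tp / (cv$tp + cv$fp)
  r0 <- c(0, rec)
  p0 <- c(prec[1], prec)
  sum(diff(r0) * (utils::head(p0, -1) + utils::tail(p0, -1)) / 2)
}

#' Compute the full metric set from predictions
#'
#' Sensitivity is `TP / (TP + FN)` on the ASD class, specificity
#' `TN / (TN + FP)`; UAR is their mean; the rank areas come from
#' trapezoidal integration of `y_score`.
#'
#' @param y_true true labels (`"ASD"`/`"NT"` or 0/1), both classes
#'   present.
#' @param y_pred predicted labels.
#' @param y_score continuous scores (optional; rank areas are `NA`
#'   without them).
#' @return A [metric_set()].
#' @examples
#' compute_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0), c(0.9, 0.4, 0.3, 0.1))
#' @export
compute_metrics <- function(y_true, y_pred, y_score = NULL) {
  y <- label_to_binary(y_true)
  if (length(unique(y)) < 2) stop("rank metrics undefined for single-class y_true")
  p <- label_to_binary(y_pred)
  sens <- sum(p == 1 & y == 1) / sum(y == 1)
  spec <- sum(p == 0 & y == 0) / sum(y == 0)
  if (is.null(y_score)) {
    metric_set(sens, spec)
  } else {
    metric_set(sens, spec, auc_roc(y, y_score), auc_pr(y, y_score))
  }
}
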