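#' Cross-tabulate predictions against truth
#'
#' Standard 2x2 confusion counts with the anticancer class (label 1) as
#' positive.
#'
#' @param predicted,truth Binary 0/1 vectors of equal length.
#' @return List of class `confusion_counts` with elements `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
confusion <- function(predicted, truth) {
  predicted <- as.integer(predicted)
  truth <- as.integer(truth)
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length")
  }
  if (!all(c(predicted, truth) %in% c(0L, 1L))) stop("labels must be binary 0/1")
  structure(list(
    tp = sum(predicted == 1L & truth == 1L),
    tn = sum(predicted == 0L & truth == 0L),
    fp = sum(predicted == 1L & truth == 0L),
    fn = sum(predicted == 0L & truth == 1L)
  ), class = "confusion_counts")
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen
#' positive sample is scored above a randomly chosen negative one, with
#' ties counted 1/2. Exactly equivalent to brute-force pair counting.
#'
#' @param scores Positive-class scores.
#' @param truth Binary 0/1 labels aligned with `scores`.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, truth) {
  truth <- as.integer(truth)
  stopifnot(length(scores) == length(truth))
  n_pos <- sum(truth == 1L)
  n_neg <- sum(truth == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("AUC requires both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Compute the evaluation metric set from confusion counts
#'
#' Sensitivity `Sn = TP/(TP+FN) * 100`, specificity `Sp = TN/(TN+FP) * 100`,
#' accuracy `ACC = (TP+TN)/n * 100`, Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` (0 when any
#' denominator factor is zero), and optionally AUC from per-sample scores.
#'
#' @param counts A `confusion_counts` object.
#' @param scores Optional positive-class scores (for AUC).
#' @param truth Optional 0/1 labels aligned with `scores`.
#' @return List of class `metric_set`: `acc`, `mcc`, `sn`, `sp` (percent
#'   scales for acc/sn/sp) and `auc` (`NA` if no scores supplied).
#' @export
compute_metrics <- function(counts, scores = NULL, truth = NULL) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  if (tp + fn == 0L) stop("metric Sn undefined: no positive samples")
  if (tn + fp == 0L) stop("metric Sp undefined: no negative samples")
  n <- tp + tn + fp + fn
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else
    (tp * tn - fp * fn) / sqrt(denom)
  auc <- NA_real_
  if (!is.null(scores)) {
    if (is.null(truth)) stop("AUC requires truth labels alongside scores")
    auc <- auc_score(scores, truth)
  }
  structure(list(
    acc = 100 * (tp + tn) / n,
    mcc = mcc,
    sn = 100 * tp / (tp + fn),
    sp = 100 * tn / (tn + fp),
    auc = auc
  ), class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("ACC %.1f%%  MCC %.3f  Sn %.1f%%  Sp %.1f%%  AUC %s\n",
              x$acc, x$mcc, x$sn, x$sp,
              if (is.na(x$auc)) "-" else sprintf("%.3f", x$auc)))
  invisible(x)
}

#' Gini impurity of a class-proportion vector
#'
#' `1 - sum(p_k^2)` for proportions on the simplex; 0 for a pure node,
#' maximal at the uniform distribution. This is the node impurity behind
#' mean-decrease-impurity feature importance in tree ensembles.
#'
#' @param p Non-negative proportions summing to 1.
#' @return The impurity, in \[0, 1).
#' @export
gini_index <- function(p) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("proportions must be non-negative and sum to 1")
  }
  1 - sum(p^2)
}
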