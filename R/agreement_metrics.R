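#' Confusion table for binary quality labels
#'
#' "Accepted" (label 1) is the positive class throughout the package.
#'
#' @param predicted predicted binary labels (0/1 or logical).
#' @param truth reference binary labels.
#' @return an object of class `confusion_table` with counts `tp, fp, fn, tn`.
#' @export
confusion_table <- function(predicted, truth) {
  predicted <- as.integer(as.logical(predicted))
  truth <- as.integer(as.logical(truth))
  if (length(predicted) != length(truth))
    qc_abort("length mismatch between predictions and truth", "dscqc_length_mismatch")
  if (anyNA(predicted) || anyNA(truth))
    qc_abort("labels must be binary with no missing values", "dscqc_invalid_labels")
  structure(
    list(tp = sum(predicted == 1L & truth == 1L),
         fp = sum(predicted == 1L & truth == 0L),
         fn = sum(predicted == 0L & truth == 1L),
         tn = sum(predicted == 0L & truth == 0L)),
    class = "confusion_table"
  )
}

#' Binary classification performance metrics
#'
#' Sensitivity, specificity, precision and classification error from a
#' confusion table. Metrics with a zero denominator are returned as `NA` and
#' flagged in `undefined`, never raised as errors.
#'
#' @param ct a [confusion_table()].
#' @return a list (class `metric_set`) with `sensitivity`, `specificity`,
#'   `precision` (proportions), `classification_error` (percent), `auc`
#'   (`NA` here; filled in by score-based evaluations) and `undefined`
#'   (character vector of flagged metrics).
#' @export
binary_metrics <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  total <- ct$tp + ct$fp + ct$fn + ct$tn
  if (total == 0L)
    qc_abort("empty confusion table", "dscqc_empty_confusion")
  undefined <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0L) { undefined <<- c(undefined, name); NA_real_ } else num / den
  }
  out <- list(
    sensitivity = ratio(ct$tp, ct$tp + ct$fn, "sensitivity"),
    specificity = ratio(ct$tn, ct$tn + ct$fp, "specificity"),
    precision = ratio(ct$tp, ct$tp + ct$fp, "precision"),
    classification_error = 100 * (ct$fp + ct$fn) / total,
    auc = NA_real_
  )
  out$undefined <- undefined
  class(out) <- "metric_set"
  out
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("<metrics: sens %.2f, spec %.2f, prec %.2f, error %.1f%%, AUC %s>\n",
              x$sensitivity, x$specificity, x$precision, x$classification_error,
              if (is.na(x$auc)) "-" else sprintf("%.2f", x$auc)))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Computed via the Mann-Whitney statistic using midranks, so tied scores
#' contribute half: AUC = P(score+ > score-) + 0.5 P(score+ = score-). This
#' equals the trapezoidal area under the ROC curve swept over all score
#' thresholds.
#'
#' @param scores continuous scores, larger meaning more likely positive.
#' @param labels binary labels (1 = positive/accepted).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels))
    qc_abort("length mismatch between scores and labels", "dscqc_length_mismatch")
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    qc_abort("single-class input: AUC undefined", "dscqc_single_class")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Percentage disagreement between two raters
#'
#' @param r1,r2 binary rating vectors of equal length.
#' @return percentage of positions where the raters disagree.
#' @export
percent_disagreement <- function(r1, r2) {
  if (length(r1) != length(r2))
    qc_abort("length mismatch between raters", "dscqc_length_mismatch")
  if (length(r1) == 0L)
    qc_abort("empty ratings", "dscqc_invalid_labels")
  100 * sum(r1 != r2) / length(r1)
}

#' Cohen's kappa for two binary raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` on the
#' 2-category table, with `p_e` the product-of-marginals chance agreement.
#' Returns exactly 1 when observed agreement is perfect; if both marginals
#' are degenerate (`p_e = 1` with `p_o = 1`) the conventional value 1 is
#' returned with a warning.
#'
#' @inheritParams percent_disagreement
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(r1, r2) {
  if (length(r1) != length(r2))
    qc_abort("length mismatch between raters", "dscqc_length_mismatch")
  n <- length(r1)
  if (n < 2L)
    qc_abort("need at least 2 rating pairs", "dscqc_invalid_labels")
  r1 <- as.integer(as.logical(r1)); r2 <- as.integer(as.logical(r2))
  p_o <- mean(r1 == r2)
  if (p_o == 1) {
    p_e <- mean(r1) * mean(r2) + (1 - mean(r1)) * (1 - mean(r2))
    if (p_e == 1) warning("degenerate marginals: kappa = 1 by convention")
    return(1)
  }
  p_e <- mean(r1) * mean(r2) + (1 - mean(r1)) * (1 - mean(r2))
  (p_o - p_e) / (1 - p_e)
}

#' Interrater agreement report
#'
#' Percentage disagreement and Cohen's kappa overall and, optionally, within
#' user-defined subgroups (e.g. field strength).
#'
#' @inheritParams percent_disagreement
#' @param groups optional vector of group labels, same length as the ratings.
#' @return a `data.frame` with columns `group`, `n_pairs`,
#'   `percent_disagreement`, `kappa`.
#' @export
agreement_report <- function(r1, r2, groups = NULL) {
  if (length(r1) != length(r2))
    qc_abort("length mismatch between raters", "dscqc_length_mismatch")
  one <- function(name, idx) {
    data.frame(group = name, n_pairs = length(idx),
               percent_disagreement = percent_disagreement(r1[idx], r2[idx]),
               kappa = cohens_kappa(r1[idx], r2[idx]),
               stringsAsFactors = FALSE)
  }
  out <- one("all", seq_along(r1))
  if (!is.null(groups)) {
    stopifnot(length(groups) == length(r1))
    for (g in unique(groups)) out <- rbind(out, one(as.character(g), which(groups == g)))
  }
  out
}
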