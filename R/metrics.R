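#' Confusion matrix and per-class performance metrics
#'
#' Computes the true-by-predicted confusion matrix and, for every class,
#' the one-vs-rest counts and metrics: `sensitivity = 100 * TP / (TP + FN)`,
#' `specificity = 100 * TN / (TN + FP)`, reported as percentages to two
#' decimals. Overall `accuracy = 100 * trace / total`. Predicted labels
#' never seen in the truth get their own confusion-matrix column.
#'
#' @param truth True class labels.
#' @param estimate Predicted class labels (same length).
#' @return Object of class `class_metrics`: `confusion` (table),
#'   `by_class` (tibble with TP/FP/TN/FN and metrics), `accuracy`, `n`.
#' @export
class_metrics <- function(truth, estimate) {
  truth <- as.character(truth)
  estimate <- as.character(estimate)
  if (length(truth) != length(estimate)) {
    stop("truth and estimate must have equal length")
  }
  lv <- sort(unique(c(truth, estimate)))
  confusion <- table(truth = factor(truth, lv), predicted = factor(estimate, lv))
  n <- length(truth)
  by_class <- purrr::map_dfr(sort(unique(truth)), function(cls) {
    tp <- sum(truth == cls & estimate == cls)
    fn <- sum(truth == cls & estimate != cls)
    fp <- sum(truth != cls & estimate == cls)
    tn <- sum(truth != cls & estimate != cls)
    tibble::tibble(
      class = cls, tp = tp, fp = fp, tn = tn, fn = fn,
      sensitivity = round(100 * tp / (tp + fn), 2),
      specificity = round(100 * tn / (tn + fp), 2)
    )
  })
  structure(
    list(confusion = confusion, by_class = by_class,
         accuracy = round(100 * sum(truth == estimate) / n, 2), n = n),
    class = "class_metrics"
  )
}

#' @export
print.class_metrics <- function(x, ...) {
  cat("<class_metrics> accuracy", sprintf("%.2f%%", x$accuracy),
      "on", x$n, "samples\n")
  print(x$confusion)
  print(as.data.frame(x$by_class), row.names = FALSE)
  invisible(x)
}

#' ROC curve and AUROC for a binary score
#'
#' Sweeps every distinct score as a threshold (predicting positive above
#' it) and accumulates the true/false positive rates; the area under the
#' curve is computed by the trapezoid rule, so tied scores contribute half
#' a concordant pair and the AUROC equals the Mann-Whitney U statistic
#' divided by `n_pos * n_neg`.
#'
#' @param scores Numeric score per sample (larger = more positive-like).
#' @param labels Class label per sample.
#' @param positive The label counted as positive.
#' @return Object of class `roc_result`: `curve` (tibble `threshold`,
#'   `fpr`, `tpr`), `auroc`, `positive`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels, positive) {
  stopifnot(length(scores) == length(labels))
  is_pos <- labels == positive
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("both a positive and a negative sample are required")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- is_pos[ord]
  # collapse tied scores into single curve points
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(pos)[last_of_tie]
  fp <- cumsum(!pos)[last_of_tie]
  curve <- tibble::tibble(
    threshold = c(Inf, s[last_of_tie]),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
  auroc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                    utils::tail(curve$tpr, -1)) / 2)
  structure(
    list(curve = curve, auroc = auroc, positive = positive,
         n_pos = n_pos, n_neg = n_neg),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUROC %.4f (positive = %s; %d+/%d-)\n",
              x$auroc, x$positive, x$n_pos, x$n_neg))
  invisible(x)
}
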