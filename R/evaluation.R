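#' Confusion-matrix metrics for binary predictions
#'
#' Computes tp/fp/tn/fn, accuracy, precision, recall and F1 (the harmonic
#' mean of precision and recall). Undefined ratios (zero denominator) are
#' reported as 0 together with an explicit `undefined` flag, so sweep
#' tables stay numeric.
#'
#' @param predicted Character vector of predicted labels.
#' @param actual Character vector of true labels, same length.
#' @param positive Name of the positive class (default `"pos"`).
#' @return An object of class `"metrics_report"`: a list with `tp`, `fp`,
#'   `tn`, `fn`, `accuracy`, `precision`, `recall`, `f1`, and `undefined`
#'   (character vector naming any zero-denominator metrics).
#' @export
classification_metrics <- function(predicted, actual, positive = "pos") {
  if (length(predicted) == 0) stop("empty input")
  if (length(predicted) != length(actual)) {
    stop("predicted and actual must have the same length")
  }
  pp <- predicted == positive
  ap <- actual == positive
  tp <- sum(pp & ap); fp <- sum(pp & !ap)
  fn <- sum(!pp & ap); tn <- sum(!pp & !ap)
  undefined <- character()
  safe_div <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      0
    } else num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- safe_div(2 * precision * recall, precision + recall, "f1")
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = (tp + tn) / length(predicted),
                 precision = precision, recall = recall, f1 = f1,
                 undefined = undefined),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("tp=%d fp=%d tn=%d fn=%d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("accuracy=%.4f precision=%.4f recall=%.4f f1=%.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  if (length(x$undefined)) {
    cat("undefined (reported as 0):", paste(x$undefined, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn,
             accuracy = x$accuracy, precision = x$precision,
             recall = x$recall, f1 = x$f1)
}

#' F1 score from precision and recall
#'
#' The harmonic mean `2 * precision * recall / (precision + recall)`;
#' 0 when both inputs are 0.
#'
#' @param precision,recall Numeric vectors in \[0, 1\].
#' @return Numeric vector of F1 scores.
#' @export
#' @examples
#' f1_score(0.6912, 0.7853)
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Empirical ROC curve and AUC
#'
#' Sweeps the decision threshold over the distinct score values (ties
#' grouped at one threshold), from `+Inf` (predict nothing positive, point
#' (0,0)) down to the minimum score (predict everything positive, point
#' (1,1)). AUC is the trapezoidal area under the resulting step curve.
#'
#' @param scores Continuous decision scores (higher = more positive).
#' @param labels True labels.
#' @param positive Name of the positive class (default `"pos"`).
#' @return An object of class `"roc_curve"`: list with `thresholds`
#'   (descending, starting at `Inf`), `fpr`, `tpr`, `auc`, `n_pos`,
#'   `n_neg`.
#' @export
roc_curve <- function(scores, labels, positive = "pos") {
  stopifnot(length(scores) == length(labels))
  y <- labels == positive
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) {
    stop("roc_curve() needs at least one positive and one negative label")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- y[ord]
  # cumulative counts at each distinct score (ties grouped)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_tie]
  fp <- cumsum(!y)[last_of_tie]
  structure(list(
    thresholds = c(Inf, s[last_of_tie]),
    tpr = c(0, tp / n_pos),
    fpr = c(0, fp / n_neg),
    auc = trapezoid_auc(c(0, fp / n_neg), c(0, tp / n_pos)),
    n_pos = n_pos, n_neg = n_neg
  ), class = "roc_curve")
}

trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d thresholds, %d pos / %d neg, AUC = %.4f\n",
              length(x$thresholds), x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

#' @export
as.data.frame.roc_curve <- function(x, ...) {
  data.frame(threshold = x$thresholds, fpr = x$fpr, tpr = x$tpr)
}

#' Project metrics onto a more imbalanced test set
#'
#' Formalizes the class-imbalance argument: at a fixed decision threshold
#' the true-positive and false-positive *rates* are properties of the
#' model, so enlarging the negative pool by a multiplier scales the
#' absolute number of false positives while true positives stay fixed --
#' precision (and with it F1) must fall even though recall is unchanged.
#'
#' @param tpr True-positive rate (recall) in (0, 1].
#' @param fpr False-positive rate in (0, 1].
#' @param n_pos,n_neg Base counts of positive and negative examples.
#' @param multiplier Negative-pool multiplier (>= 1).
#' @return List with `tp`, `fp`, `precision`, `recall`, `f1`,
#'   `n_neg_scaled`.
#' @export
#' @examples
#' imbalance_f1_projection(0.9, 0.05, 1000, 1000, 5)
imbalance_f1_projection <- function(tpr, fpr, n_pos = 1000, n_neg = 1000,
                                    multiplier = 1) {
  if (tpr <= 0 || tpr > 1 || fpr <= 0 || fpr > 1) {
    stop("tpr and fpr must lie in (0, 1]")
  }
  if (multiplier < 1) stop("multiplier must be >= 1")
  tp <- tpr * n_pos
  fp <- fpr * n_neg * multiplier
  precision <- tp / (tp + fp)
  list(tp = tp, fp = fp, precision = precision, recall = tpr,
       f1 = f1_score(precision, tpr), n_neg_scaled = n_neg * multiplier)
}
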