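#' Confusion counts from predictions
#'
#' @param pred,truth 0/1 vectors of equal length.
#' @return Object of class `confusion_counts` with fields `TP`, `TN`,
#'   `FP`, `FN`.
#' @export
confusion_counts <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), all(pred %in% 0:1),
            all(truth %in% 0:1))
  structure(list(TP = sum(pred == 1L & truth == 1L),
                 TN = sum(pred == 0L & truth == 0L),
                 FP = sum(pred == 1L & truth == 0L),
                 FN = sum(pred == 0L & truth == 1L)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall, F1 (harmonic mean of precision and
#' recall) and the Matthews correlation coefficient. By documented
#' convention a metric whose denominator is zero (e.g. precision with no
#' predicted positives) is reported as 0 with a warning.
#'
#' @param counts A [confusion_counts()]; alternatively pass `TP`, `TN`,
#'   `FP`, `FN` directly.
#' @param TP,TN,FP,FN Non-negative integer counts (ignored when `counts`
#'   is given).
#' @return Named list: `accuracy`, `precision`, `recall`, `f1`, `mcc`.
#' @export
compute_metrics <- function(counts = NULL, TP = 0, TN = 0, FP = 0, FN = 0) {
  if (!is.null(counts)) {
    stopifnot(inherits(counts, "confusion_counts"))
    TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  }
  if (any(c(TP, TN, FP, FN) < 0)) stop("negative counts")
  total <- TP + TN + FP + FN
  if (total == 0) stop("empty confusion table")
  zdiv <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); reporting 0", what))
      return(0)
    }
    num / den
  }
  acc <- (TP + TN) / total
  prec <- zdiv(TP, TP + FP, "precision")
  rec <- zdiv(TP, TP + FN, "recall")
  f1 <- if (prec + rec == 0) {
    warning("f1 undefined (precision + recall = 0); reporting 0")
    0
  } else 2 * prec * rec / (prec + rec)
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- if (mcc_den == 0) {
    warning("mcc undefined (zero denominator); reporting 0")
    0
  } else (TP * TN - FP * FN) / mcc_den
  list(accuracy = acc, precision = prec, recall = rec, f1 = f1, mcc = mcc)
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the (false positive rate, true positive rate)
#' curve swept over all score thresholds. Tied scores are grouped into a
#' single threshold, which makes the trapezoidal area identical to the
#' midrank (Mann-Whitney) formulation `U / (n1 * n0)`.
#'
#' @param scores Numeric scores, larger = more positive.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1),
            all(is.finite(scores)))
  P <- sum(labels == 1L)
  N <- sum(labels == 0L)
  if (P == 0 || N == 0) stop("AUC undefined: only one class present")
  rc <- roc_points(scores, labels)
  sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + utils::tail(rc$tpr, -1)) / 2)
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return Data frame of `threshold`, `fpr`, `tpr` (including the (0,0)
#'   and (1,1) endpoints), suitable for plotting or export.
#' @export
roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  keep <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tied block
  data.frame(threshold = c(Inf, s[keep]),
             fpr = c(0, fp[keep] / sum(labels == 0L)),
             tpr = c(0, tp[keep] / sum(labels == 1L)))
}

#' Metrics from probabilistic predictions
#'
#' Thresholds the positive-class probability at 0.5 (equivalently, the
#' softmax argmax) for the confusion-based metrics, and computes AUC from
#' the raw probabilities.
#'
#' @param p_pos Positive-class probabilities.
#' @param labels 0/1 labels.
#' @return Named list: `accuracy`, `precision`, `recall`, `f1`, `auc`,
#'   `mcc` (AUC is `NA` when only one class is present).
#' @export
metrics_from_predictions <- function(p_pos, labels) {
  m <- compute_metrics(confusion_counts(as.integer(p_pos >= 0.5), labels))
  m$auc <- if (length(unique(labels)) == 2L) roc_auc(p_pos, labels) else NA_real_
  m[c("accuracy", "precision", "recall", "f1", "auc", "mcc")]
}
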