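# Confusion-count bookkeeping and the five performance metrics:
# accuracy, precision, sensitivity, specificity, F1.

#' One-vs-rest confusion counts
#'
#' Reduces integer predictions to a binary confusion table against a
#' designated positive ("abnormal") class: TP are positives predicted
#' positive, TN negatives predicted negative, FP negatives predicted
#' positive, FN positives predicted negative.
#'
#' @param y_true,y_pred Integer label vectors of equal length.
#' @param positive_class The label counted as positive.
#' @return A list with integer fields `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred, positive_class) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  tp <- sum(y_true == positive_class & y_pred == positive_class)
  tn <- sum(y_true != positive_class & y_pred != positive_class)
  fp <- sum(y_true != positive_class & y_pred == positive_class)
  fn <- sum(y_true == positive_class & y_pred != positive_class)
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

# Ratio with the degenerate-denominator convention: 0 with a warning.
safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("%s undefined (zero denominator); reporting 0", what),
            call. = FALSE)
    return(0)
  }
  num / den
}

#' Performance metrics from confusion counts
#'
#' Computes accuracy (TP+TN over all), precision (TP over predicted
#' positive), sensitivity (TP over actual positive), specificity (TN over
#' actual negative) and the F1 score (harmonic mean of precision and
#' sensitivity). Ratios with a zero denominator are reported as 0 with a
#' warning so a degenerate fold never aborts a cross-validation run.
#'
#' @param counts Output of [confusion_counts()].
#' @return Named numeric vector with elements `accuracy`, `precision`,
#'   `sensitivity`, `specificity`, `f1`, all in `[0, 1]`.
#' @examples
#' score(list(TP = 9, TN = 8, FP = 1, FN = 2))["accuracy"]  # 0.85
#' @export
score <- function(counts) {
  with(counts, {
    total <- TP + TN + FP + FN
    if (total == 0) stop("empty confusion table")
    accuracy    <- (TP + TN) / total
    precision   <- safe_ratio(TP, TP + FP, "precision")
    sensitivity <- safe_ratio(TP, TP + FN, "sensitivity")
    specificity <- safe_ratio(TN, FP + TN, "specificity")
    f1 <- if (precision + sensitivity == 0) 0 else
      2 * precision * sensitivity / (precision + sensitivity)
    c(accuracy = accuracy, precision = precision, sensitivity = sensitivity,
      specificity = specificity, f1 = f1)
  })
}

#' Multi-class metrics with macro averaging
#'
#' Accuracy is the overall fraction of correct predictions. Precision,
#' sensitivity, specificity and F1 are computed one-vs-rest per class and
#' macro-averaged (unweighted mean over classes). For two classes with
#' `macro = FALSE` (the default used by the cross-validation driver for
#' binary tasks), the metrics are the plain one-vs-rest values against
#' `positive`.
#'
#' @param y_true,y_pred Integer vectors with labels in `0..n_classes-1`.
#' @param n_classes Number of task classes.
#' @param positive Positive class for the binary path (default
#'   `n_classes - 1`, the seizure class when the scheme ends in E).
#' @param macro Force macro averaging even for 2 classes.
#' @return Named numeric vector as in [score()], plus attribute
#'   `"per_class"`: the per-class one-vs-rest metric matrix.
#' @export
multiclass_score <- function(y_true, y_pred, n_classes,
                             positive = n_classes - 1L,
                             macro = n_classes > 2L) {
  if (n_classes < 2L) stop("n_classes must be >= 2")
  per_class <- vapply(0:(n_classes - 1L), function(cl) {
    score(confusion_counts(y_true, y_pred, cl))
  }, numeric(5))
  colnames(per_class) <- paste0("class", 0:(n_classes - 1L))
  if (macro) {
    out <- c(accuracy = mean(y_true == y_pred),
             rowMeans(per_class)[c("precision", "sensitivity",
                                   "specificity", "f1")])
  } else {
    out <- per_class[, positive + 1L]
    out["accuracy"] <- mean(y_true == y_pred)
  }
  attr(out, "per_class") <- per_class
  out
}
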