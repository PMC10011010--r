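#' Classification metrics from a confusion matrix
#'
#' Accuracy is correct classifications over total attempts;
#' `F1 = 2 * precision * recall / (precision + recall)`, defined as 0 when
#' `precision + recall = 0` (or when either is undefined because its
#' denominator is empty).
#'
#' @param tp,fp,tn,fn confusion counts with class 1 ("failure") positive.
#' @return A `cv_metrics` list: `confusion`, `accuracy`, `precision`,
#'   `recall`, `f1`.
#' @export
metrics_from_confusion <- function(tp, fp, tn, fn) {
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty confusion matrix")
  accuracy <- (tp + tn) / total
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 accuracy = accuracy, precision = precision,
                 recall = recall, f1 = f1),
            class = "cv_metrics")
}

#' @export
print.cv_metrics <- function(x, ...) {
  cat(sprintf(
    "accuracy %.3f | precision %.3f | recall %.3f | F1 %.3f  (TP %d FP %d TN %d FN %d)\n",
    x$accuracy, x$precision, x$recall, x$f1,
    x$confusion["TP"], x$confusion["FP"], x$confusion["TN"],
    x$confusion["FN"]))
  invisible(x)
}
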