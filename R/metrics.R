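#' Tally a binary confusion matrix
#'
#' Counts true positives, true negatives, false positives and false
#' negatives for two-valued label vectors, given which value is the
#' positive class.
#'
#' @param true_labels,predicted_labels Equal-length vectors over at most
#'   two distinct values.
#' @param positive The label value treated as positive.
#' @return An object of class `confusion_counts` with integer fields
#'   `tp`, `tn`, `fp`, `fn` and the recorded `positive` label.
#' @export
count_confusion <- function(true_labels, predicted_labels, positive) {
  if (length(true_labels) != length(predicted_labels)) {
    stop_input("label vectors differ in length")
  }
  tl <- as.character(true_labels)
  pl <- as.character(predicted_labels)
  vals <- unique(c(tl, pl))
  if (length(vals) > 2L) {
    stop_input("more than two distinct label values: ",
               paste(vals, collapse = ", "))
  }
  positive <- as.character(positive)
  tpos <- tl == positive
  ppos <- pl == positive
  structure(list(tp = sum(tpos & ppos), tn = sum(!tpos & !ppos),
                 fp = sum(!tpos & ppos), fn = sum(tpos & !ppos),
                 positive = positive),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Computes the four standard diagnostic metrics:
#' accuracy = (TP+TN)/(TP+TN+FP+FN), precision = TP/(TP+FP),
#' recall = TP/(TP+FN), and F1 = 2*precision*recall/(precision+recall).
#' A zero denominator (no positive predictions, or no positive samples)
#' yields 0 for the affected metric, with a flag recorded in the report so
#' the degeneracy is not silently lost; F1 is 0 when precision + recall
#' is 0.
#'
#' @param counts A [count_confusion()] result.
#' @return An object of class `eval_report`: `counts`, `accuracy`,
#'   `precision`, `recall`, `f1`, `undefined` (character vector naming any
#'   zero-denominator metrics), `positive`.
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  n <- counts$tp + counts$tn + counts$fp + counts$fn
  if (n == 0) stop_input("no evaluated samples (all counts zero)")
  undefined <- character(0)
  precision <- if (counts$tp + counts$fp == 0) {
    undefined <- c(undefined, "precision"); 0
  } else counts$tp / (counts$tp + counts$fp)
  recall <- if (counts$tp + counts$fn == 0) {
    undefined <- c(undefined, "recall"); 0
  } else counts$tp / (counts$tp + counts$fn)
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  structure(list(counts = counts,
                 accuracy = (counts$tp + counts$tn) / n,
                 precision = precision, recall = recall, f1 = f1,
                 undefined = undefined, positive = counts$positive),
            class = "eval_report")
}

#' Evaluate predictions against true labels
#'
#' Convenience wrapper: [count_confusion()] then [compute_metrics()].
#'
#' @inheritParams count_confusion
#' @return An `eval_report`.
#' @export
classification_report <- function(true_labels, predicted_labels, positive) {
  compute_metrics(count_confusion(true_labels, predicted_labels, positive))
}

#' @export
print.eval_report <- function(x, ...) {
  c_ <- x$counts
  cat("Confusion (positive = ", x$positive, "): TP=", c_$tp, " TN=", c_$tn,
      " FP=", c_$fp, " FN=", c_$fn, "\n", sep = "")
  cat(sprintf("accuracy %.4f | precision %.4f | recall %.4f | F1 %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  if (length(x$undefined)) {
    cat("note: zero denominator, reported as 0:",
        paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}
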