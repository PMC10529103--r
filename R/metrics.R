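#' Binary confusion matrix
#'
#' Counts true/false positives and negatives relative to a chosen positive
#' class. The minority ("depressed") class is the conventional positive for
#' the screening task, but either convention can be reported.
#'
#' @param predictions,labels equal-length integer vectors of predicted and
#'   true class ids (binary task).
#' @param positive_class class id counted as positive (default 1).
#' @return Object of class `fbanet_confusion` with fields `tp`, `tn`, `fp`,
#'   `fn`, `positive_class`, and `normalized`, the row-normalized 2x2 matrix
#'   (rows = truth, columns = prediction).
#' @examples
#' confusion(c(1, 0, 1), c(1, 0, 0), positive_class = 1)
#' @export
confusion <- function(predictions, labels, positive_class = 1L) {
  if (length(predictions) != length(labels)) stopf("predictions and labels disagree in length")
  pp <- predictions == positive_class
  lp <- labels == positive_class
  cm <- structure(
    list(tp = sum(pp & lp), tn = sum(!pp & !lp), fp = sum(pp & !lp), fn = sum(!pp & lp),
         positive_class = as.integer(positive_class)),
    class = "fbanet_confusion")
  raw <- matrix(c(cm$tn, cm$fp, cm$fn, cm$tp), 2, 2, byrow = TRUE,
                dimnames = list(truth = c("negative", "positive"),
                                predicted = c("negative", "positive")))
  rs <- rowSums(raw)
  cm$normalized <- raw / ifelse(rs > 0, rs, 1)
  cm$counts <- raw
  cm
}

#' @export
print.fbanet_confusion <- function(x, ...) {
  cat(sprintf("Confusion matrix (positive class = %d)\n", x$positive_class))
  print(x$counts)
  invisible(x)
}

#' Confusion-matrix metrics
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)` and F1 `2TP/(2TP+FP+FN)` (the harmonic mean of precision and
#' recall). Ratios with a zero denominator are reported as 0 and recorded in
#' the `undefined` field.
#'
#' @param cm an [confusion()] object.
#' @return Object of class `fbanet_metrics` with fields `accuracy`,
#'   `precision`, `recall`, `f1`, `undefined`.
#' @examples
#' compute_metrics(confusion(c(1, 1, 0, 0), c(1, 0, 1, 0)))
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "fbanet_confusion"))
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  if (total == 0) stopf("empty confusion matrix")
  undefined <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); return(0) }
    num / den
  }
  acc <- (cm$tp + cm$tn) / total
  prec <- ratio(cm$tp, cm$tp + cm$fp, "precision")
  rec <- ratio(cm$tp, cm$tp + cm$fn, "recall")
  f1 <- ratio(2 * cm$tp, 2 * cm$tp + cm$fp + cm$fn, "f1")
  if (length(undefined) > 0)
    warning(sprintf("zero denominator, reported as 0: %s",
                    paste(undefined, collapse = ", ")), call. = FALSE)
  structure(list(accuracy = acc, precision = prec, recall = rec, f1 = f1,
                 undefined = undefined),
            class = "fbanet_metrics")
}

#' @export
print.fbanet_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f  precision %.4f  recall %.4f  f1 %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Aggregate per-fold metrics
#'
#' Arithmetic mean and elementwise maximum of each metric across folds (the
#' validation-average / validation-max reporting convention for k-fold
#' cross-validation).
#'
#' @param reports non-empty list of `fbanet_metrics` objects.
#' @return List with `average` and `max`, each an `fbanet_metrics`.
#' @export
aggregate_folds <- function(reports) {
  if (length(reports) == 0) stopf("non-empty list of metric reports required")
  fields <- c("accuracy", "precision", "recall", "f1")
  vals <- sapply(reports, function(r) unlist(r[fields]))
  mk <- function(v) structure(as.list(v), names = fields, class = "fbanet_metrics")
  list(average = mk(rowMeans(vals)), max = mk(apply(vals, 1, max)))
}
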