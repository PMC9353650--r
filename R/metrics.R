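# Confusion-count bookkeeping and Acc/Pre/Rec/F1 for imbalanced multi-class
# evaluation. Per-class counts are one-vs-rest; precision/recall/F1 are
# macro-averaged by default (each class weighs equally, which is what the
# class imbalance in these datasets calls for).

#' One-vs-rest confusion counts per class
#'
#' @param y_true,y_pred Equal-length 1-based integer label vectors.
#' @param n_classes Number of classes.
#' @return Object of class `"confusion_counts"`: an `n_classes x 4` matrix
#'   with columns `TP`, `FP`, `FN`, `TN`; each row sums to `length(y_true)`.
#' @export
confusion_counts <- function(y_true, y_pred, n_classes) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  if (length(y_true) == 0L) stop("no samples to evaluate")
  if (any(y_true < 1L | y_true > n_classes) || any(y_pred < 1L | y_pred > n_classes)) {
    stop(sprintf("labels must lie in [1, %d]", n_classes))
  }
  n <- length(y_true)
  out <- matrix(0L, n_classes, 4L,
                dimnames = list(paste0("class", seq_len(n_classes)),
                                c("TP", "FP", "FN", "TN")))
  for (k in seq_len(n_classes)) {
    tp <- sum(y_true == k & y_pred == k)
    fp <- sum(y_true != k & y_pred == k)
    fn <- sum(y_true == k & y_pred != k)
    out[k, ] <- c(tp, fp, fn, n - tp - fp - fn)
  }
  structure(out, n = n, class = c("confusion_counts", class(out)))
}

safe_div <- function(num, den) ifelse(den > 0, num / den, 0)

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Accuracy is `(TP + TN) / n` pooled over the one-vs-rest counts for a binary
#' problem, i.e. the fraction of correctly classified samples; for more than
#' two classes it is the standard multi-class accuracy `sum(TP) / n`.
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and their harmonic mean F1 are
#' computed per class and then averaged — unweighted (`"macro"`, the default)
#' or by class prevalence (`"weighted"`). Undefined ratios (zero denominator)
#' are reported as 0 and flagged.
#'
#' @param counts A [confusion_counts()] object, or a named vector/list with
#'   entries `TP`, `TN`, `FP`, `FN` describing a single one-vs-rest class.
#' @param average `"macro"` or `"weighted"`.
#' @return Object of class `"metrics_report"`: list with `Acc`, `Pre`, `Rec`,
#'   `F1` (fractions in \[0,1\]), `per_class` (matrix of per-class Pre/Rec/F1),
#'   and `zero_division` (logical flag).
#' @export
metrics_report <- function(counts, average = c("macro", "weighted")) {
  average <- match.arg(average)
  if (!inherits(counts, "confusion_counts")) {
    counts <- as.list(counts)
    stopifnot(all(c("TP", "TN", "FP", "FN") %in% names(counts)))
    m <- matrix(as.numeric(counts[c("TP", "FP", "FN", "TN")]), 1L, 4L,
                dimnames = list("class1", c("TP", "FP", "FN", "TN")))
    counts <- structure(m, n = sum(m), class = c("confusion_counts", class(m)))
  }
  n <- attr(counts, "n")
  if (n == 0L) stop("empty report: no evaluated samples")
  cnt <- unclass(counts)
  acc <- if (nrow(cnt) > 2L) {
    sum(cnt[, "TP"]) / n
  } else {
    # binary / single one-vs-rest row: pooled (TP + TN) over all counts
    sum(cnt[, "TP"] + cnt[, "TN"]) / sum(cnt)
  }
  pre <- safe_div(cnt[, "TP"], cnt[, "TP"] + cnt[, "FP"])
  rec <- safe_div(cnt[, "TP"], cnt[, "TP"] + cnt[, "FN"])
  f1 <- safe_div(2 * pre * rec, pre + rec)
  zero_div <- any((cnt[, "TP"] + cnt[, "FP"]) == 0) ||
    any((cnt[, "TP"] + cnt[, "FN"]) == 0) || any((pre + rec) == 0)
  w <- if (average == "macro") {
    rep(1 / nrow(cnt), nrow(cnt))
  } else {
    prev <- cnt[, "TP"] + cnt[, "FN"]
    prev / sum(prev)
  }
  structure(list(Acc = acc, Pre = sum(w * pre), Rec = sum(w * rec),
                 F1 = sum(w * f1),
                 per_class = cbind(Pre = pre, Rec = rec, F1 = f1),
                 zero_division = zero_div),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Acc: %.2f%%  Pre: %.2f%%  Rec: %.2f%%  F1: %.2f%%\n",
              100 * x$Acc, 100 * x$Pre, 100 * x$Rec, 100 * x$F1))
  if (x$zero_division) cat("(zero-division cases reported as 0)\n")
  invisible(x)
}

#' Serialize a metrics report as key-value lines
#'
#' @param x A `"metrics_report"`.
#' @param path Optional file to write to.
#' @return Character vector of `key<TAB>value` lines, percentages to 2
#'   decimals, invisibly when written to a file.
#' @export
format_metrics <- function(x, path = NULL) {
  lines <- sprintf("%s\t%.2f", c("Acc", "Pre", "Rec", "F1"),
                   100 * c(x$Acc, x$Pre, x$Rec, x$F1))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
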