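#' Confusion-matrix counts
#'
#' Tabulates true/false positives/negatives of a binary prediction with
#' respect to a declared positive class. The package default treats
#' `"normal"` as positive (precision then measures how trustworthy a
#' "healthy" call is); flip `positive` for the anomaly-as-positive
#' convention.
#'
#' @param truth,predicted equal-length binary label vectors.
#' @param positive the label counted as positive (default `"normal"`).
#' @return An object of class `confusion_counts`: list with integer `tp`,
#'   `tn`, `fp`, `fn`.
#' @export
confusion <- function(truth, predicted, positive = "normal") {
  if (length(truth) != length(predicted)) {
    stop("`truth` and `predicted` differ in length")
  }
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  classes <- unique(c(truth, predicted))
  if (length(classes) > 2L) stop("labels are not binary")
  if (!positive %in% classes) {
    # legal degenerate case: positive class absent from both vectors
    classes <- c(classes, positive)
  }
  tpos <- truth == positive
  ppos <- predicted == positive
  structure(
    list(
      tp = sum(tpos & ppos), tn = sum(!tpos & !ppos),
      fp = sum(!tpos & ppos), fn = sum(tpos & !ppos),
      positive = positive
    ),
    class = "confusion_counts"
  )
}

#' @rdname confusion
#' @param tp,tn,fp,fn non-negative integer cell counts.
#' @export
confusion_counts <- function(tp, tn, fp, fn, positive = "normal") {
  cells <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("counts must be non-negative integers")
  }
  structure(
    c(lapply(as.list(cells), as.integer), list(positive = positive)),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf(
    "<confusion_counts> tp=%d tn=%d fp=%d fn=%d (positive: %s)\n",
    x$tp, x$tn, x$fp, x$fn, x$positive
  ))
  invisible(x)
}

.metric_total <- function(c) c$tp + c$tn + c$fp + c$fn

#' Classification metrics from confusion counts
#'
#' `accuracy_score` is (tp + tn) / total; `precision_score` is
#' tp / (tp + fp); `recall_score` is tp / (tp + fn); `f1_score` is the
#' harmonic mean of precision and recall. A metric whose denominator is
#' zero is reported as 0 and carries the attribute `degenerate = TRUE`, so
#' batch evaluations never abort.
#'
#' @param counts a [confusion_counts()] object.
#' @return Scalar in \[0, 1\].
#' @export
accuracy_score <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- .metric_total(counts)
  if (total == 0L) stop("no observations")
  (counts$tp + counts$tn) / total
}

.ratio_or_zero <- function(num, den) {
  if (den == 0) structure(0, degenerate = TRUE) else num / den
}

#' @rdname accuracy_score
#' @export
precision_score <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  .ratio_or_zero(counts$tp, counts$tp + counts$fp)
}

#' @rdname accuracy_score
#' @export
recall_score <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  .ratio_or_zero(counts$tp, counts$tp + counts$fn)
}

#' @rdname accuracy_score
#' @export
f1_score <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  p <- precision_score(counts)
  r <- recall_score(counts)
  .ratio_or_zero(2 * as.numeric(p) * as.numeric(r), as.numeric(p) + as.numeric(r))
}

#' Full metrics report
#'
#' @param counts a [confusion_counts()] object.
#' @param model_name,seed optional metadata recorded in the report.
#' @return An object of class `metrics_report`: the four metrics, the
#'   counts, and any metadata.
#' @export
metrics_report <- function(counts, model_name = NULL, seed = NULL) {
  stopifnot(inherits(counts, "confusion_counts"))
  structure(
    list(
      accuracy = accuracy_score(counts),
      precision = precision_score(counts),
      recall = recall_score(counts),
      f1 = f1_score(counts),
      counts = counts,
      model_name = model_name,
      seed = seed
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  hdr <- if (is.null(x$model_name)) "" else paste0(" [", x$model_name, "]")
  cat(sprintf("<metrics_report>%s positive=%s\n", hdr, x$counts$positive))
  cat(sprintf(
    "  accuracy %.4f | precision %.4f | recall %.4f | F1 %.4f\n",
    x$accuracy, x$precision, x$recall, x$f1
  ))
  cat(sprintf(
    "  tp=%d tn=%d fp=%d fn=%d\n",
    x$counts$tp, x$counts$tn, x$counts$fp, x$counts$fn
  ))
  invisible(x)
}

#' Evaluate a detector or classifier on a labeled test set
#'
#' Applies [detect()] (for a [fit_detector()] result) or
#' [classify_sequence()] with a 0.5 cutoff (for a [train_lstm()] model) to
#' every record and summarizes the four metrics against the true binary
#' labels.
#'
#' @param object a `threshold_detector` or `lstm_model`.
#' @param test a binarized, normalized [beat_dataset()].
#' @param positive the positive class (default `"normal"`).
#' @return A [metrics_report()].
#' @export
evaluate_detector <- function(object, test, positive = "normal") {
  stopifnot(inherits(test, "beat_dataset"))
  if (n_beats(test) == 0L) stop("test dataset is empty")
  if (is.null(test$binary_label)) {
    stop("test dataset must be binarized (see binarize_labels())")
  }
  predicted <- if (inherits(object, "threshold_detector")) {
    detect(object, test)
  } else if (inherits(object, "lstm_model")) {
    ifelse(classify_sequence(test$values, object) >= 0.5, "normal", "anomalous")
  } else {
    stop("`object` must be a threshold_detector or lstm_model")
  }
  name <- if (inherits(object, "lstm_model")) "lstm" else object$model_type
  metrics_report(
    confusion(test$binary_label, predicted, positive = positive),
    model_name = name
  )
}

#' Write / read a metrics report as key-value text
#'
#' @param report a [metrics_report()].
#' @param path output file.
#' @return `write_metrics_report()` returns `path` invisibly;
#'   `read_metrics_report()` returns a named list of the stored fields.
#' @export
write_metrics_report <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  lines <- c(
    sprintf("model\t%s", if (is.null(report$model_name)) "NA" else report$model_name),
    sprintf("positive\t%s", report$counts$positive),
    sprintf("accuracy\t%.10g", report$accuracy),
    sprintf("precision\t%.10g", report$precision),
    sprintf("recall\t%.10g", report$recall),
    sprintf("f1\t%.10g", report$f1),
    sprintf("tp\t%d", report$counts$tp),
    sprintf("tn\t%d", report$counts$tn),
    sprintf("fp\t%d", report$counts$fp),
    sprintf("fn\t%d", report$counts$fn)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_metrics_report
#' @export
read_metrics_report <- function(path) {
  rows <- strsplit(readLines(path), "\t", fixed = TRUE)
  out <- lapply(rows, `[[`, 2L)
  names(out) <- vapply(rows, `[[`, "", 1L)
  for (k in c("accuracy", "precision", "recall", "f1")) {
    out[[k]] <- as.numeric(out[[k]])
  }
  for (k in c("tp", "tn", "fp", "fn")) out[[k]] <- as.integer(out[[k]])
  out
}
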