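#' Construct a labeled beat dataset
#'
#' A `beat_dataset` holds `n` fixed-length heartbeat records as the rows of a
#' numeric matrix, together with the raw integer class label of each record
#' and, once [binarize_labels()] has been applied, a derived binary label
#' (`"normal"` / `"anomalous"`).
#'
#' @param values numeric matrix, one beat per row.
#' @param label integer vector of raw class ids, one per row.
#' @param binary_label optional character vector of `"normal"`/`"anomalous"`.
#' @return An object of class `beat_dataset`: a list with elements `values`,
#'   `label`, `binary_label` and `series_length`.
#' @seealso [read_beats()], [binarize_labels()], [split_dataset()]
#' @export
beat_dataset <- function(values, label, binary_label = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (one beat per row)")
  }
  label <- as.integer(label)
  if (length(label) != nrow(values)) {
    stop("`label` must have one entry per row of `values`")
  }
  if (!is.null(binary_label)) {
    binary_label <- as.character(binary_label)
    if (length(binary_label) != nrow(values)) {
      stop("`binary_label` must have one entry per record")
    }
    bad <- setdiff(unique(binary_label), c("normal", "anomalous"))
    if (length(bad) > 0) {
      stop("binary labels must be 'normal' or 'anomalous'")
    }
  }
  structure(
    list(
      values = unname(values),
      label = label,
      binary_label = binary_label,
      series_length = ncol(values)
    ),
    class = "beat_dataset"
  )
}

#' Number of records in a beat dataset
#' @param dataset a [beat_dataset()].
#' @return integer count.
#' @export
n_beats <- function(dataset) {
  stopifnot(inherits(dataset, "beat_dataset"))
  nrow(dataset$values)
}

#' Per-class record counts
#'
#' @param dataset a binarized [beat_dataset()].
#' @return Named integer vector with elements `normal` and `anomalous`.
#' @export
beat_counts <- function(dataset) {
  stopifnot(inherits(dataset, "beat_dataset"))
  if (is.null(dataset$binary_label)) {
    stop("dataset has no binary labels; call binarize_labels() first")
  }
  c(
    normal = sum(dataset$binary_label == "normal"),
    anomalous = sum(dataset$binary_label == "anomalous")
  )
}

#' @export
`[.beat_dataset` <- function(x, i, ...) {
  beat_dataset(
    x$values[i, , drop = FALSE],
    x$label[i],
    if (!is.null(x$binary_label)) x$binary_label[i]
  )
}

#' @export
print.beat_dataset <- function(x, ...) {
  cat(sprintf(
    "<beat_dataset> %d records x %d samples\n",
    n_beats(x), x$series_length
  ))
  if (!is.null(x$binary_label)) {
    cts <- beat_counts(x)
    cat(sprintf("  normal: %d  anomalous: %d\n", cts[["normal"]], cts[["anomalous"]]))
  } else {
    cat("  raw labels:", paste(sort(unique(x$label)), collapse = " "), "\n")
  }
  invisible(x)
}

#' Read beats from a UCR-archive-style delimited file
#'
#' Each row is one record: an integer class label followed by
#' `series_length` numeric samples, tab- or comma-delimited (auto-detected),
#' with no header.
#'
#' @param path path to the file.
#' @param series_length expected number of samples per beat (default 140).
#' @return A [beat_dataset()] with one record per row, in file order. Binary
#'   labels are unset; apply [binarize_labels()].
#' @export
read_beats <- function(path, series_length = 140L) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no records in ", path)
  sep <- if (grepl("\t", lines[[1]], fixed = TRUE)) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  want <- series_length + 1L
  lens <- lengths(parts)
  if (any(lens != want)) {
    bad <- which(lens != want)[[1]]
    stop(sprintf(
      "row %d has %d fields, expected %d (label + %d values)",
      bad, lens[[bad]], want, series_length
    ))
  }
  num <- suppressWarnings(as.numeric(unlist(parts, use.names = FALSE)))
  if (anyNA(num)) {
    bad <- (which(is.na(num))[[1]] - 1L) %/% want + 1L
    stop(sprintf("non-numeric token in row %d", bad))
  }
  mat <- matrix(num, nrow = length(lines), ncol = want, byrow = TRUE)
  lab <- mat[, 1L]
  if (any(lab != round(lab))) {
    stop(sprintf(
      "non-integer class label in row %d", which(lab != round(lab))[[1]]
    ))
  }
  beat_dataset(mat[, -1L, drop = FALSE], as.integer(lab))
}

#' Write beats to a UCR-archive-style delimited file
#'
#' Inverse of [read_beats()]: one row per record, raw label first. Values are
#' written with enough digits to round-trip to at least 10 significant
#' figures.
#'
#' @param dataset a [beat_dataset()].
#' @param path output file path.
#' @param sep field separator, tab by default.
#' @return `path`, invisibly.
#' @export
write_beats <- function(dataset, path, sep = "\t") {
  stopifnot(inherits(dataset, "beat_dataset"))
  vals <- formatC(dataset$values, format = "g", digits = 12)
  rows <- apply(cbind(as.character(dataset$label), vals), 1L, paste,
    collapse = sep
  )
  writeLines(rows, path)
  invisible(path)
}

#' Derive binary normal/anomalous labels from raw class ids
#'
#' ECG5000 carries five raw classes; only class 1 is a normal sinus beat and
#' the four remaining classes are arrhythmic, which reproduces the benchmark's
#' 2989 normal / 2011 anomalous totals. The set of classes treated as normal
#' is configurable.
#'
#' @param dataset a [beat_dataset()].
#' @param normal_classes integer vector of raw labels mapped to `"normal"`
#'   (default `1`).
#' @return The dataset with `binary_label` filled in.
#' @export
binarize_labels <- function(dataset, normal_classes = 1L) {
  stopifnot(inherits(dataset, "beat_dataset"))
  if (length(normal_classes) == 0L) stop("`normal_classes` must be nonempty")
  bin <- ifelse(dataset$label %in% as.integer(normal_classes),
    "normal", "anomalous"
  )
  beat_dataset(dataset$values, dataset$label, bin)
}
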