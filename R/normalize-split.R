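#' Fit min-max normalization parameters on a training set
#'
#' The global minimum and maximum over all training values define the affine
#' map used by [apply_normalization()]. Fitting on the training split only
#' (and reusing the parameters for validation/test) avoids information
#' leakage; real 140-point beats span roughly \[-5, 2\] and are mapped to
#' \[0, 1\], the range of the reconstruction models' sigmoid output layer.
#'
#' @param train a nonempty [beat_dataset()].
#' @return An object of class `norm_params` with fields `min_value` and
#'   `max_value`.
#' @export
fit_normalization <- function(train) {
  stopifnot(inherits(train, "beat_dataset"))
  if (n_beats(train) == 0L) stop("training dataset is empty")
  lo <- min(train$values)
  hi <- max(train$values)
  if (hi <= lo) {
    stop("all training values are identical; min-max normalization undefined")
  }
  norm_params(lo, hi)
}

#' @rdname fit_normalization
#' @param min_value,max_value the range endpoints, `max_value > min_value`.
#' @export
norm_params <- function(min_value, max_value) {
  if (!is.finite(min_value) || !is.finite(max_value) || max_value <= min_value) {
    stop("require finite max_value > min_value")
  }
  structure(
    list(min_value = min_value, max_value = max_value),
    class = "norm_params"
  )
}

#' Apply min-max normalization
#'
#' Maps `min_value` to 0 and `max_value` to 1; values outside the fitted
#' range (possible on validation/test data) are clipped into \[0, 1\].
#'
#' @param values numeric vector or matrix.
#' @param params a `norm_params` object from [fit_normalization()].
#' @return Object of the same shape with values in \[0, 1\].
#' @export
apply_normalization <- function(values, params) {
  stopifnot(inherits(params, "norm_params"))
  out <- (values - params$min_value) / (params$max_value - params$min_value)
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Normalize every record of a dataset
#'
#' @param dataset a [beat_dataset()].
#' @inheritParams apply_normalization
#' @return The dataset with normalized `values`.
#' @export
normalize_dataset <- function(dataset, params) {
  stopifnot(inherits(dataset, "beat_dataset"))
  beat_dataset(
    apply_normalization(dataset$values, params),
    dataset$label, dataset$binary_label
  )
}

#' Split a dataset into train / validation / test parts
#'
#' Records are shuffled with the given seed and partitioned by the ratios.
#' Part sizes are `floor(n * ratio)` for train and validation, with the
#' remainder going to test, so the partition is deterministic and exhaustive.
#' The shuffle is a plain record-level permutation (not stratified by class).
#'
#' @param dataset a [beat_dataset()].
#' @param ratios three positive reals summing to 1; default `c(0.8, 0.1, 0.1)`.
#' @param seed integer RNG seed; the same seed always yields the same split.
#' @return An object of class `beat_split`: list with `train`, `validation`,
#'   `test` ([beat_dataset()]s), `ratios` and `seed`.
#' @export
split_dataset <- function(dataset, ratios = c(0.8, 0.1, 0.1), seed = 42L) {
  stopifnot(inherits(dataset, "beat_dataset"))
  if (length(ratios) != 3L || any(ratios <= 0)) {
    stop("`ratios` must be three positive numbers")
  }
  if (abs(sum(ratios) - 1) > 1e-9) stop("`ratios` must sum to 1")
  n <- n_beats(dataset)
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  n_train <- floor(n * ratios[[1]])
  n_val <- floor(n * ratios[[2]])
  idx_train <- perm[seq_len(n_train)]
  idx_val <- perm[seq_len(n_val) + n_train]
  idx_test <- perm[setdiff(seq_len(n), seq_len(n_train + n_val))]
  structure(
    list(
      train = dataset[idx_train],
      validation = dataset[idx_val],
      test = dataset[idx_test],
      ratios = ratios,
      seed = as.integer(seed)
    ),
    class = "beat_split"
  )
}

#' @export
print.beat_split <- function(x, ...) {
  cat(sprintf(
    "<beat_split> train %d / validation %d / test %d (seed %d)\n",
    n_beats(x$train), n_beats(x$validation), n_beats(x$test), x$seed
  ))
  invisible(x)
}
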