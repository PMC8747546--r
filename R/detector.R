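#' @title Reconstruction-error threshold detection
#' @description Converts a reconstruction model trained on normal beats
#'   only into a binary anomaly detector: the decision threshold is set to
#'   one standard deviation above the mean per-record reconstruction error
#'   on the normal training set, and any beat whose error exceeds the
#'   threshold is flagged anomalous.
#' @name detector
NULL

#' Distribution of per-record reconstruction errors
#'
#' @param errors numeric vector of non-negative per-record errors.
#' @param sd_type `"population"` (divide by n, the default) or `"sample"`
#'   (divide by n - 1).
#' @return A `loss_distribution` object: `errors`, `mean`, `std`, `sd_type`.
#' @export
loss_distribution <- function(errors, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  errors <- as.numeric(errors)
  if (length(errors) == 0L) stop("no errors supplied")
  if (any(errors < 0)) stop("reconstruction errors must be non-negative")
  m <- mean(errors)
  s <- if (sd_type == "population") {
    sqrt(mean((errors - m)^2))
  } else {
    sd(errors)
  }
  structure(
    list(errors = errors, mean = m, std = s, sd_type = sd_type),
    class = "loss_distribution"
  )
}

#' Per-record reconstruction errors of a model on a dataset
#'
#' One MAE per record, computed from the model's deterministic
#' reconstruction (for a VAE this decodes at `z = mu`).
#'
#' @param model anything with a [model_reconstruct()] method (an `ae_model`,
#'   a `vae_model`, or a plain reconstruction function).
#' @param dataset a normalized [beat_dataset()].
#' @inheritParams loss_distribution
#' @return A [loss_distribution()] over the dataset's records, in record
#'   order.
#' @export
per_record_errors <- function(model, dataset,
                              sd_type = c("population", "sample")) {
  stopifnot(inherits(dataset, "beat_dataset"))
  if (n_beats(dataset) == 0L) stop("dataset is empty")
  recon <- model_reconstruct(model, dataset$values)
  loss_distribution(
    per_record_mae(dataset$values, recon),
    sd_type = match.arg(sd_type)
  )
}

#' Decision threshold: mean plus one standard deviation
#'
#' `tau = mean(errors) + std(errors)`, with the population standard
#' deviation by default. Requires at least two errors so the spread is
#' defined.
#'
#' @param dist a [loss_distribution()].
#' @return Scalar threshold.
#' @export
compute_threshold <- function(dist) {
  stopifnot(inherits(dist, "loss_distribution"))
  if (length(dist$errors) < 2L) {
    stop("need at least 2 errors to set a threshold")
  }
  dist$mean + dist$std
}

#' Fit a threshold detector on normal beats
#'
#' Trains the chosen reconstruction model on the (normal-only, normalized)
#' dataset, scores the same records, and stores the mean-plus-one-SD
#' threshold. The entire procedure is controlled by `config$seed`.
#'
#' @param normals a binarized, normalized [beat_dataset()] of normal beats.
#' @param model_type `"cat_ae"` (attention autoencoder, default), `"ae"`
#'   (plain) or `"vae"`.
#' @param config a [train_config()]; for `"vae"` the default epoch count is
#'   raised to 100 unless a config is supplied explicitly.
#' @param normalization optional [norm_params()] recorded so that
#'   [detect()] inputs can be transformed identically at deployment.
#' @param sd_type standard-deviation convention, see [loss_distribution()].
#' @param ... passed on to [train_autoencoder()] or [train_vae()].
#' @return An object of class `threshold_detector`: `model`, `threshold`,
#'   `distribution` (training errors), `model_type`, `normalization`.
#' @export
fit_detector <- function(normals, model_type = c("cat_ae", "ae", "vae"),
                         config = NULL, normalization = NULL,
                         sd_type = c("population", "sample"), ...) {
  model_type <- match.arg(model_type)
  sd_type <- match.arg(sd_type)
  .check_normal_only(normals, "a threshold detector")
  if (is.null(config)) {
    config <- if (model_type == "vae") {
      train_config(epochs = 100L)
    } else {
      train_config()
    }
  }
  model <- switch(model_type,
    cat_ae = train_autoencoder(normals, arch = "cat_ae", config = config, ...),
    ae = train_autoencoder(normals, arch = "ae", config = config, ...),
    vae = train_vae(normals, config = config, ...)
  )
  dist <- per_record_errors(model, normals, sd_type = sd_type)
  structure(
    list(
      model = model,
      threshold = compute_threshold(dist),
      distribution = dist,
      model_type = model_type,
      normalization = normalization
    ),
    class = "threshold_detector"
  )
}

#' @export
print.threshold_detector <- function(x, ...) {
  cat(sprintf(
    "<threshold_detector> model=%s  tau=%.6f (mean %.6f + sd %.6f over %d normals)\n",
    x$model_type, x$threshold, x$distribution$mean, x$distribution$std,
    length(x$distribution$errors)
  ))
  invisible(x)
}

#' Classify beats as normal or anomalous
#'
#' A beat is anomalous iff its reconstruction error is strictly greater
#' than the detector's threshold; a beat scoring exactly at the threshold
#' is normal. Inputs must already be normalized to \[0, 1\] (apply the
#' detector's stored [norm_params()] first).
#'
#' @param detector a fitted [fit_detector()] object.
#' @param x a normalized beat vector, `n x T` matrix, or [beat_dataset()].
#' @return Character vector of `"normal"` / `"anomalous"`, one per record.
#' @export
detect <- function(detector, x) {
  stopifnot(inherits(detector, "threshold_detector"))
  vals <- if (inherits(x, "beat_dataset")) x$values else x
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = 1L)
  if (any(vals < 0 | vals > 1)) {
    stop(
      "input values outside [0, 1]; apply the detector's normalization ",
      "parameters before calling detect()"
    )
  }
  err <- per_record_mae(vals, model_reconstruct(detector$model, vals))
  ifelse(err > detector$threshold, "anomalous", "normal")
}

#' Reconstruction errors scored by a fitted detector
#'
#' Convenience wrapper returning the raw per-record errors a [detect()]
#' call would compare against the threshold.
#'
#' @inheritParams detect
#' @return Numeric vector of per-record MAE values.
#' @export
detector_errors <- function(detector, x) {
  stopifnot(inherits(detector, "threshold_detector"))
  vals <- if (inherits(x, "beat_dataset")) x$values else x
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = 1L)
  per_record_mae(vals, model_reconstruct(detector$model, vals))
}
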