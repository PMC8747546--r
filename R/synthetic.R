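#' @title Synthetic ECG beats
#' @description Generator of labeled synthetic heartbeats that mimic the
#'   shape, value range and class structure of real 140-point ECG beats, so
#'   the full detection pipeline can be exercised without external data.
#' @name synthetic
NULL

# Fixed P-QRS-T morphology, expressed in fractions of the series length so
# any length >= 8 works. Amplitudes are chosen so the clean prototype stays
# inside [-5, 2], the value range of real beats before normalization, with
# a deep negative S trough as in lead-II congestive-heart-failure recordings.
.ecg_components <- function(series_length) {
  L <- series_length
  comp <- function(amplitude, center_frac, width_frac) {
    list(
      amplitude = amplitude,
      center = round(center_frac * L),
      width = max(width_frac * L, 0.75)
    )
  }
  list(
    p = comp(0.50, 0.15, 0.030),
    q = comp(-1.00, 0.28, 0.012),
    r = comp(2.45, 0.33, 0.016),
    s = comp(-4.30, 0.38, 0.020),
    t = comp(1.10, 0.58, 0.055)
  )
}

.ecg_baseline <- -0.35

.check_series_length <- function(series_length) {
  if (!is.numeric(series_length) || series_length < 8) {
    stop("`series_length` must be at least 8")
  }
  as.integer(series_length)
}

# Sum-of-Gaussian-bumps waveform on samples 1..L.
.morph_curve <- function(components, series_length,
                         baseline = .ecg_baseline) {
  i <- seq_len(series_length)
  out <- rep(baseline, series_length)
  for (cm in components) {
    out <- out + cm$amplitude * exp(-((i - cm$center)^2) / (2 * cm$width^2))
  }
  out
}

#' Index of the R-peak in the synthetic prototype
#'
#' @param series_length beat length in samples (default 140).
#' @return Integer sample index of the R-wave center.
#' @export
r_peak_index <- function(series_length = 140L) {
  series_length <- .check_series_length(series_length)
  .ecg_components(series_length)$r$center
}

#' Clean synthetic normal-beat prototype
#'
#' Deterministic sum of five fixed Gaussian bumps (P wave, Q dip, R spike,
#' deep S trough, T wave) on a flat baseline. All values lie in \[-5, 2\] and
#' the global maximum sits at the R-wave center ([r_peak_index()]).
#'
#' @param series_length beat length in samples (default 140, minimum 8).
#' @return Numeric vector of length `series_length`.
#' @export
normal_prototype <- function(series_length = 140L) {
  series_length <- .check_series_length(series_length)
  .morph_curve(.ecg_components(series_length), series_length)
}

#' Kinds of synthetic beat anomaly
#' @return Character vector of supported anomaly kinds.
#' @export
anomaly_kinds <- function() {
  c("inverted_t", "widened_qrs", "shifted_r", "flat_segment")
}

# Returns modified components; flat_segment is handled as a curve-level
# post-process in .anomaly_curve.
.anomaly_components <- function(components, kind) {
  switch(kind,
    inverted_t = {
      components$t$amplitude <- -components$t$amplitude
      components
    },
    widened_qrs = {
      for (k in c("q", "r", "s")) components[[k]]$width <- 2 * components[[k]]$width
      components
    },
    shifted_r = {
      shift <- max(round(0.07 * 140), 1L)
      for (k in c("q", "r", "s")) components[[k]]$center <- components[[k]]$center + shift
      components
    },
    flat_segment = components,
    stop("unknown anomaly kind: ", kind)
  )
}

.anomaly_curve <- function(components, kind, series_length,
                           baseline = .ecg_baseline) {
  curve <- .morph_curve(.anomaly_components(components, kind), series_length,
    baseline = baseline
  )
  if (kind == "flat_segment") {
    tc <- components$t
    lo <- max(1L, round(tc$center - 3 * tc$width))
    hi <- min(series_length, round(tc$center + 3 * tc$width))
    curve[lo:hi] <- baseline
  }
  curve
}

#' Clean synthetic anomalous-beat prototype
#'
#' Deterministic morphological perturbation of [normal_prototype()]:
#' `inverted_t` negates the T-wave amplitude, `widened_qrs` doubles the
#' Q/R/S widths, `shifted_r` displaces the QRS complex ~7% of the beat to
#' the right, and `flat_segment` replaces the T-wave region with baseline.
#'
#' @param kind one of [anomaly_kinds()].
#' @inheritParams normal_prototype
#' @return Numeric vector of length `series_length`.
#' @export
anomaly_prototype <- function(kind = anomaly_kinds(), series_length = 140L) {
  kind <- match.arg(kind)
  series_length <- .check_series_length(series_length)
  .anomaly_curve(.ecg_components(series_length), kind, series_length)
}

#' Generate a labeled synthetic beat dataset
#'
#' Each record is its class prototype with per-component multiplicative
#' amplitude jitter and additive i.i.d. Gaussian sample noise. Normal beats
#' get raw label 1, anomalous beats raw label 2; binary labels are set.
#' Fully deterministic under `seed`.
#'
#' @param n_normal,n_anomalous record counts (non-negative).
#' @param anomaly_kind one of [anomaly_kinds()].
#' @param noise_sd standard deviation of the additive sample noise
#'   (default 0.05, a mild corruption relative to the ~6-unit beat range).
#' @param amplitude_jitter standard deviation of the per-component relative
#'   amplitude perturbation (default 0.05).
#' @param series_length beat length in samples (default 140).
#' @param seed integer RNG seed (default 42).
#' @return A binarized [beat_dataset()] with `n_normal + n_anomalous` records.
#' @examples
#' ds <- generate_beats(10, 5, seed = 1)
#' beat_counts(ds)
#' @export
generate_beats <- function(n_normal, n_anomalous,
                           anomaly_kind = anomaly_kinds(),
                           noise_sd = 0.05, amplitude_jitter = 0.05,
                           series_length = 140L, seed = 42L) {
  anomaly_kind <- match.arg(anomaly_kind)
  series_length <- .check_series_length(series_length)
  stopifnot(n_normal >= 0, n_anomalous >= 0, noise_sd >= 0, amplitude_jitter >= 0)
  base <- .ecg_components(series_length)
  n <- n_normal + n_anomalous
  withr::with_seed(as.integer(seed), {
    values <- matrix(0, nrow = n, ncol = series_length)
    is_anom <- rep(c(FALSE, TRUE), c(n_normal, n_anomalous))
    for (rec in seq_len(n)) {
      comps <- base
      for (k in names(comps)) {
        comps[[k]]$amplitude <- comps[[k]]$amplitude *
          (1 + rnorm(1L, 0, amplitude_jitter))
      }
      curve <- if (is_anom[[rec]]) {
        .anomaly_curve(comps, anomaly_kind, series_length)
      } else {
        .morph_curve(comps, series_length)
      }
      values[rec, ] <- curve + rnorm(series_length, 0, noise_sd)
    }
    beat_dataset(
      values,
      label = ifelse(is_anom, 2L, 1L),
      binary_label = ifelse(is_anom, "anomalous", "normal")
    )
  })
}
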