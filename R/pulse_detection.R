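#' Normalized cross-correlation between two equal-length windows
#'
#' Computes the linear (zero-padded, non-circular) cross-correlation
#' \deqn{r_{xy}(l) = \frac{\sum_n x(n)\,y(n-l)}{\sqrt{\sum_n x(n)^2 \sum_n y(n)^2}},
#'   \quad l = 0, \pm 1, \ldots, \pm(N-1),}
#' between the filtered ECG `x` and filtered acceleration `y` of one
#' compression-free window, evaluated over the full lag range via FFT.
#' Under the default `"energy_sqrt"` normalization every value lies in
#' \eqn{[-1, 1]} (Cauchy--Schwarz) and the statistic is invariant to positive
#' rescaling of either channel. The alternative `"energy_product"`
#' normalization divides by the plain product of the two signal energies; it
#' is not scale-invariant and is retained only for comparison.
#'
#' Sign convention: with this definition, an acceleration waveform that is a
#' copy of the ECG delayed by `d` samples peaks at lag `-d`, i.e. negative
#' peak lags mean the acceleration lags the ECG.
#'
#' @param x,y Numeric vectors of identical length `N >= 2`, each with at
#'   least one nonzero sample.
#' @param normalization `"energy_sqrt"` (default) or `"energy_product"`.
#' @return A tibble of class `cpr_xcorr` with columns `lag`
#'   (`-(N-1) ... N-1`) and `value`, and attributes `normalization` and `n`.
#' @examples
#' cc <- normalized_xcorr(c(1, 0, 0), c(0, 1, 0))
#' peak_correlation(cc)
#' @export
normalized_xcorr <- function(x, y,
                             normalization = c("energy_sqrt", "energy_product")) {
  normalization <- match.arg(normalization)
  check_numeric_series(x, "x", min_len = 2L)
  check_numeric_series(y, "y", min_len = 2L)
  if (length(x) != length(y)) {
    abort(sprintf("`x` and `y` must have the same length (%d vs %d).",
                  length(x), length(y)), class = "ccpulse_shape_error")
  }
  ex <- sum(x^2)
  ey <- sum(y^2)
  if (ex == 0 || ey == 0) {
    abort("Correlation undefined: one input is identically zero.",
          class = "ccpulse_degenerate_input_error")
  }
  n <- length(x)
  m <- stats::nextn(2L * n - 1L, 2)
  fx <- fft(c(x, numeric(m - n)))
  fy <- fft(c(y, numeric(m - n)))
  r <- Re(fft(fx * Conj(fy), inverse = TRUE)) / m
  vals <- c(r[seq(m - n + 2L, m)], r[seq_len(n)])
  denom <- switch(normalization,
                  energy_sqrt = sqrt(ex * ey),
                  energy_product = ex * ey)
  out <- tibble(lag = seq(-(n - 1L), n - 1L), value = vals / denom)
  structure(out, normalization = normalization, n = n,
            class = c("cpr_xcorr", class(out)))
}

#' Peak of a cross-correlation sequence
#'
#' Returns the signed maximum of the normalized cross-correlation (the peak
#' correlation coefficient, CCp) and the lag at which it occurs. Exact ties
#' are broken toward the lag of smallest absolute value, then toward the
#' negative lag.
#'
#' @param cc A `cpr_xcorr` tibble from [normalized_xcorr()] (any data frame
#'   with `lag` and `value` columns works).
#' @return One-row tibble with `ccp` and `peak_lag` (in samples).
#' @export
peak_correlation <- function(cc) {
  if (!all(c("lag", "value") %in% names(cc)) || nrow(cc) == 0L) {
    abort("`cc` must have columns `lag` and `value`.",
          class = "ccpulse_shape_error")
  }
  ord <- order(-cc$value, abs(cc$lag), cc$lag)
  best <- ord[1L]
  tibble(ccp = cc$value[best], peak_lag = as.integer(cc$lag[best]))
}

#' CCp of one compression-free segment
#'
#' The full per-segment detection statistic: the ECG is band-passed to
#' 0.2--45 Hz, the acceleration to 0.5--7.5 Hz (both 4th-order Butterworth,
#' zero-phase), and the peak of their normalized cross-correlation is
#' returned.
#'
#' @param ecg Numeric vector, raw ECG slice (mV).
#' @param acc Numeric vector of the same length, raw acceleration slice
#'   (m/s^2).
#' @param sample_rate_hz Sampling rate in Hz.
#' @inheritParams normalized_xcorr
#' @return One-row tibble with `ccp` and `peak_lag`.
#' @export
ccp_for_segment <- function(ecg, acc, sample_rate_hz,
                            normalization = "energy_sqrt") {
  if (length(ecg) != length(acc)) {
    abort("Segment channels must have equal length.",
          class = "ccpulse_shape_error")
  }
  x <- preprocess_ecg(ecg, sample_rate_hz)
  y <- preprocess_acc(acc, sample_rate_hz)
  peak_correlation(normalized_xcorr(x, y, normalization = normalization))
}

#' Threshold decision on the detection statistic
#'
#' Declares a spontaneous pulse present when the statistic strictly exceeds
#' the threshold.
#'
#' @param result Data frame with a `ccp` column (e.g. from
#'   [ccp_for_segment()] or [detect_pulses()]).
#' @param threshold Decision threshold, either a number or a
#'   `threshold_model` from [optimize_threshold()].
#' @return `result` with columns `decision`
#'   (`"pulse_present"`/`"pulse_absent"`) and `threshold_used` added.
#' @export
detect_pulse <- function(result, threshold) {
  thr <- if (inherits(threshold, "threshold_model")) threshold$threshold else threshold
  if (!is.numeric(thr) || length(thr) != 1L || !is.finite(thr)) {
    abort("`threshold` must be a single finite number or a threshold_model.",
          class = "ccpulse_config_error")
  }
  mutate(result,
         decision = ifelse(.data$ccp > thr, "pulse_present", "pulse_absent"),
         threshold_used = thr)
}

#' Score every segment of a nested segment table
#'
#' Maps [ccp_for_segment()] over a nested segment tibble and (optionally)
#' applies a decision threshold.
#'
#' @param segments Nested tibble with `segment_id` and list-columns `ecg`,
#'   `acc` ([extract_segments()] / [generate_dataset()]).
#' @param sample_rate_hz Sampling rate; defaults to the table attribute.
#' @param threshold Optional decision threshold (number or
#'   `threshold_model`).
#' @inheritParams normalized_xcorr
#' @return Tibble with `segment_id`, `ccp`, `peak_lag` and, when a threshold
#'   is given, `decision` and `threshold_used`.
#' @export
detect_pulses <- function(segments, sample_rate_hz = NULL, threshold = NULL,
                          normalization = "energy_sqrt") {
  fs <- sample_rate_hz %||% attr(segments, "sample_rate_hz")
  check_sample_rate(fs)
  out <- purrr::map2(segments$ecg, segments$acc,
                     ~ ccp_for_segment(.x, .y, fs, normalization = normalization))
  out <- dplyr::bind_cols(tibble(segment_id = segments$segment_id),
                          dplyr::bind_rows(out))
  if (!is.null(threshold)) out <- detect_pulse(out, threshold)
  out
}

#' Optimize a decision threshold on a training split
#'
#' Scans every candidate threshold (midpoints between consecutive distinct
#' sorted feature values, plus one candidate below the minimum and one above
#' the maximum) under the rule "positive iff value > threshold" and selects
#' the candidate with the highest training accuracy. Accuracy ties are broken
#' toward the candidate with the higher sensitivity, then toward the smallest
#' threshold.
#'
#' @param values Numeric feature values (MAP, CCp or heart rate).
#' @param labels Labels with positive class `"PR"` and negative `"PEA"`
#'   (character or factor), same length as `values`.
#' @param feature Name of the feature being thresholded (metadata).
#' @return An object of class `threshold_model`: a list with `feature`,
#'   `threshold`, `direction`, `training_accuracy`, `training_sensitivity`,
#'   `training_specificity`, `n_pr`, `n_pea`. Has [tidy()] and [glance()]
#'   methods.
#' @examples
#' optimize_threshold(c(0.1, 0.2, 0.8, 0.9), c("PEA", "PEA", "PR", "PR"))
#' @export
optimize_threshold <- function(values, labels, feature = "CCp") {
  check_numeric_series(values, "values")
  labels <- as.character(labels)
  if (length(labels) != length(values)) {
    abort("`values` and `labels` must have equal length.",
          class = "ccpulse_shape_error")
  }
  if (!all(labels %in% c("PR", "PEA"))) {
    abort("`labels` must be 'PR' or 'PEA'.", class = "ccpulse_annotation_error")
  }
  pos <- labels == "PR"
  n_pr <- sum(pos)
  n_pea <- sum(!pos)
  if (n_pr == 0L || n_pea == 0L) {
    abort("Threshold training needs both classes present.",
          class = "ccpulse_degenerate_training_error")
  }
  v <- sort(unique(values))
  candidates <- c(v[1] - 1, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2,
                  v[length(v)] + 1)
  stats_at <- vapply(candidates, function(t) {
    pred <- values > t
    tp <- sum(pred & pos)
    tn <- sum(!pred & !pos)
    c(acc = (tp + tn) / length(values), sens = tp / n_pr)
  }, numeric(2))
  ord <- order(-stats_at["acc", ], -stats_at["sens", ], candidates)
  best <- ord[1L]
  pred <- values > candidates[best]
  structure(
    list(feature = feature,
         threshold = candidates[best],
         direction = "greater_is_positive",
         training_accuracy = unname(stats_at["acc", best]),
         training_sensitivity = unname(stats_at["sens", best]),
         training_specificity = sum(!pred & !pos) / n_pea,
         n_pr = n_pr, n_pea = n_pea),
    class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("<threshold_model> %s > %.4g => pulse present\n",
              x$feature, x$threshold))
  cat(sprintf("  trained on %d PR / %d PEA: accuracy %.3f, sensitivity %.3f, specificity %.3f\n",
              x$n_pr, x$n_pea, x$training_accuracy, x$training_sensitivity,
              x$training_specificity))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a threshold model
#'
#' @param x A `threshold_model`.
#' @param ... Unused.
#' @return One-row tibble with the feature, threshold, decision direction and
#'   training performance.
#' @export
tidy.threshold_model <- function(x, ...) {
  tibble(feature = x$feature, threshold = x$threshold,
         direction = x$direction,
         training_accuracy = x$training_accuracy,
         training_sensitivity = x$training_sensitivity,
         training_specificity = x$training_specificity)
}

#' @rdname tidy.threshold_model
#' @export
glance.threshold_model <- function(x, ...) {
  tibble(threshold = x$threshold, training_accuracy = x$training_accuracy,
         n_pr = x$n_pr, n_pea = x$n_pea)
}
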