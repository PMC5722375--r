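#' Butterworth band-pass filtering of physiological channels
#'
#' `bandpass()` applies a Butterworth band-pass filter to one channel of a
#' resuscitation recording. By default the filter is run forward and backward
#' (zero-phase), because any group delay would shift the ECG-to-acceleration
#' lag structure that the pulse detector measures. `preprocess_ecg()` and
#' `preprocess_acc()` are the two fixed configurations used throughout the
#' package: 0.2--45 Hz for the ECG and 0.5--7.5 Hz for the chest acceleration,
#' both 4th-order.
#'
#' Edge handling in zero-phase mode: the signal is extended at both ends by
#' odd reflection over a pad of three filter state lengths before the
#' forward-backward pass, and the pad is stripped from the output. Low
#' cut-offs near 0.2 Hz have time constants of the order of a second, so the
#' first and last fraction of a second of a short window still carries some
#' transient; tests of steady-state gain therefore probe the interior of a
#' long signal.
#'
#' @param x Numeric vector, one uniformly sampled channel.
#' @param sample_rate_hz Sampling rate in Hz (300 in the reference acquisition setup).
#' @param low_cut_hz,high_cut_hz Band edges in Hz; must satisfy
#'   `0 < low < high < sample_rate_hz / 2`.
#' @param order Filter order of the Butterworth prototype (default 4).
#' @param zero_phase If `TRUE` (default), forward-backward filtering with no
#'   group delay and squared magnitude response; if `FALSE`, a single causal
#'   pass.
#' @return Numeric vector of the same length as `x`.
#' @examples
#' fs <- 300
#' t <- seq(0, 3, by = 1 / fs)
#' x <- sin(2 * pi * 2 * t) + 0.5 * sin(2 * pi * 60 * t)
#' y <- bandpass(x, fs, 0.5, 7.5)
#' @export
bandpass <- function(x, sample_rate_hz, low_cut_hz, high_cut_hz,
                     order = 4L, zero_phase = TRUE) {
  check_sample_rate(sample_rate_hz)
  nyq <- sample_rate_hz / 2
  if (!is.numeric(low_cut_hz) || !is.numeric(high_cut_hz) ||
      low_cut_hz <= 0 || high_cut_hz <= low_cut_hz || high_cut_hz >= nyq) {
    abort(sprintf(
      "Band edges must satisfy 0 < low < high < Nyquist (%.6g Hz); got [%g, %g].",
      nyq, low_cut_hz, high_cut_hz), class = "ccpulse_config_error")
  }
  if (order < 1) {
    abort("`order` must be >= 1.", class = "ccpulse_config_error")
  }
  check_numeric_series(x, "x")

  flt <- signal::butter(order, c(low_cut_hz, high_cut_hz) / nyq, type = "pass")
  state_len <- length(flt$b) - 1L
  if (length(x) <= 3L * state_len) {
    abort(sprintf(
      "Signal too short to filter: need more than %d samples, got %d.",
      3L * state_len, length(x)), class = "ccpulse_length_error")
  }

  if (!zero_phase) {
    return(as.numeric(signal::filter(flt, x)))
  }

  n <- length(x)
  pad <- 3L * state_len
  # odd reflection keeps level and slope continuous at the joins
  head_ext <- 2 * x[1L] - x[seq(pad + 1L, 2L)]
  tail_ext <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  xp <- c(head_ext, x, tail_ext)
  y <- as.numeric(signal::filter(flt, xp))
  y <- rev(as.numeric(signal::filter(flt, rev(y))))
  y[seq(pad + 1L, pad + n)]
}

#' @rdname bandpass
#' @param ecg Numeric vector, raw ECG in mV.
#' @export
preprocess_ecg <- function(ecg, sample_rate_hz, order = 4L, zero_phase = TRUE) {
  bandpass(ecg, sample_rate_hz, 0.2, 45, order = order, zero_phase = zero_phase)
}

#' @rdname bandpass
#' @param acc Numeric vector, raw chest acceleration in m/s^2.
#' @export
preprocess_acc <- function(acc, sample_rate_hz, order = 4L, zero_phase = TRUE) {
  bandpass(acc, sample_rate_hz, 0.5, 7.5, order = order, zero_phase = zero_phase)
}

#' Closed-form Butterworth band-pass magnitude response
#'
#' Squared magnitude response of the digital Butterworth band-pass obtained by
#' bilinear transform, evaluated through the analog prototype at the prewarped
#' frequency. For a zero-phase (forward-backward) filter the end-to-end gain
#' is this value; a single causal pass has gain equal to its square root.
#'
#' @inheritParams bandpass
#' @param freq_hz Frequencies (Hz) at which to evaluate the response.
#' @return Numeric vector of squared-magnitude gains in `[0, 1]`.
#' @export
butter_bandpass_gain <- function(freq_hz, sample_rate_hz, low_cut_hz,
                                 high_cut_hz, order = 4L) {
  check_sample_rate(sample_rate_hz)
  prewarp <- function(f) 2 * sample_rate_hz * tan(pi * f / sample_rate_hz)
  omega <- prewarp(freq_hz)
  o1 <- prewarp(low_cut_hz)
  o2 <- prewarp(high_cut_hz)
  w <- (omega^2 - o1 * o2) / (omega * (o2 - o1))
  1 / (1 + w^(2 * order))
}
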