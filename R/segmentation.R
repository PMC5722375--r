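#' Moving-RMS envelope of the chest acceleration
#'
#' Root-mean-square of the mean-removed acceleration over a centred moving
#' window. During active chest compressions the envelope sits around
#' 46/sqrt(2) ~ 33 m/s^2, while compression pauses stay near the background
#' level of a few m/s^2 or less, so a fixed threshold separates the two
#' regimes cleanly.
#'
#' @param acc Numeric vector, chest acceleration in m/s^2.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param window_s Window length in seconds (default 0.1). Shorter windows
#'   resolve compression-edge timing more sharply at the cost of a more
#'   ragged envelope inside a compression burst.
#' @return Numeric vector of the same length as `acc`.
#' @export
acc_envelope <- function(acc, sample_rate_hz, window_s = 0.1) {
  check_numeric_series(acc, "acc")
  check_sample_rate(sample_rate_hz)
  if (!is.numeric(window_s) || length(window_s) != 1L || window_s <= 0) {
    abort("`window_s` must be a single positive number.",
          class = "ccpulse_config_error")
  }
  w <- max(1L, round(window_s * sample_rate_hz))
  if (w < 1L) {
    abort("Envelope window shorter than one sample.",
          class = "ccpulse_config_error")
  }
  x2 <- (acc - mean(acc))^2
  n <- length(x2)
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w - 1L - half_lo
  # centred moving mean via cumulative sums; windows truncated at the edges
  cs <- c(0, cumsum(x2))
  lo <- pmax(seq_len(n) - half_lo, 1L)
  hi <- pmin(seq_len(n) + half_hi, n)
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Detect compression pauses from the acceleration envelope
#'
#' Finds maximal runs where the acceleration envelope stays below
#' `threshold_ms2` for at least `min_pause_s`. These hands-off intervals are
#' the only windows in which the pulse detector operates.
#'
#' @inheritParams acc_envelope
#' @param threshold_ms2 Envelope threshold in m/s^2 (default 10, between the
#'   compression and the pulse-oscillation amplitude regimes).
#' @param min_pause_s Minimum pause duration in seconds (default 3).
#' @return A tibble with one row per pause: `start_idx` (1-based, inclusive),
#'   `end_idx` (exclusive) and `duration_s`.
#' @export
detect_pauses <- function(acc, sample_rate_hz, threshold_ms2 = 10,
                          min_pause_s = 3, window_s = 0.1) {
  check_numeric_series(acc, "acc")
  check_sample_rate(sample_rate_hz)
  if (threshold_ms2 <= 0) {
    abort("`threshold_ms2` must be positive.", class = "ccpulse_config_error")
  }
  if (min_pause_s <= 0) {
    abort("`min_pause_s` must be positive.", class = "ccpulse_config_error")
  }
  if (length(acc) < min_pause_s * sample_rate_hz) {
    abort("Signal shorter than one minimum pause.",
          class = "ccpulse_length_error")
  }
  env <- acc_envelope(acc, sample_rate_hz, window_s)
  quiet <- env < threshold_ms2
  r <- rle(quiet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths >= min_pause_s * sample_rate_hz)
  tibble(
    start_idx = starts[keep],
    end_idx = ends[keep] + 1L,
    duration_s = r$lengths[keep] / sample_rate_hz
  )
}

#' Extract fixed-length compression-free segments
#'
#' Cuts one analysis window per qualifying pause, anchored at the pause start
#' (optionally shifted by a guard offset), with `n_samples =
#' round(duration_s * sample_rate_hz)` -- 900 samples for the default 3 s at
#' 300 Hz. Pauses shorter than `duration_s` (after the guard) yield no
#' segment and are reported via a message.
#'
#' @param rec Recording tibble with columns `time_s`, `ecg_mv`, `abp_mmhg`,
#'   `acc_ms2` ([read_recording()] / [gen_recording()]).
#' @param pauses Pause table from [detect_pauses()].
#' @param duration_s Segment length in seconds (default 3).
#' @param guard_s Offset after pause onset before the segment starts
#'   (default 0).
#' @param sample_rate_hz Sampling rate; defaults to the recording attribute.
#' @param quiet Suppress the skipped-pause message.
#' @return A nested tibble with one row per segment: `segment_id`,
#'   `source_record`, `start_idx`, `n_samples` and list-columns `ecg`, `abp`,
#'   `acc` holding the raw channel slices. Attribute `sample_rate_hz` is set.
#' @export
extract_segments <- function(rec, pauses, duration_s = 3, guard_s = 0,
                             sample_rate_hz = NULL, quiet = FALSE) {
  fs <- sample_rate_hz %||% recording_sample_rate(rec)
  check_sample_rate(fs)
  if (duration_s <= 0) {
    abort("`duration_s` must be positive.", class = "ccpulse_config_error")
  }
  n_samples <- round(duration_s * fs)
  guard <- round(guard_s * fs)
  record_id <- attr(rec, "record_id") %||% "record"

  rows <- vector("list", nrow(pauses))
  n_skipped <- 0L
  for (i in seq_len(nrow(pauses))) {
    start <- pauses$start_idx[i] + guard
    if (start + n_samples > pauses$end_idx[i]) {
      n_skipped <- n_skipped + 1L
      next
    }
    idx <- seq(start, length.out = n_samples)
    rows[[i]] <- tibble(
      segment_id = sprintf("%s_seg%03d", record_id, i),
      source_record = record_id,
      start_idx = start,
      n_samples = n_samples,
      ecg = list(rec$ecg_mv[idx]),
      abp = list(rec$abp_mmhg[idx]),
      acc = list(rec$acc_ms2[idx])
    )
  }
  if (!quiet && n_skipped > 0L) {
    rlang::inform(sprintf("Skipped %d pause(s) shorter than %.3g s.",
                          n_skipped, duration_s + guard_s))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(segment_id = character(), source_record = character(),
                  start_idx = integer(), n_samples = integer(),
                  ecg = list(), abp = list(), acc = list())
  }
  attr(out, "sample_rate_hz") <- fs
  out
}
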