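#' QRS detection in a compression-free ECG window
#'
#' A compact energy-based detector in the spirit of Pan--Tompkins: the ECG is
#' band-passed to a QRS-dominant 8--20 Hz band (zero-phase, so no fiducial
#' shift; the band sits above T-wave energy so tall post-arrest T waves do
#' not trigger), differentiated, squared and integrated over a 150 ms moving
#' window. Two guards separate QRS activity from disorganized rhythms: a
#' spectral gate requires an appreciable share of the 3--30 Hz signal energy
#' to lie above 10 Hz (the sharp QRS deflection has it; VF-like band-limited
#' oscillation does not, so such windows yield no QRS and are classified
#' disorganized downstream), and energy peaks must exceed both a fraction of
#' the window maximum and a multiple of the window median (which rejects
#' temporally continuous energy such as broadband noise). Detections closer
#' than the refractory period keep the stronger peak; the fiducial point is
#' the midpoint of the positive and negative extrema of the filtered ECG
#' within 80 ms of each energy peak, i.e. the centre of the biphasic
#' deflection.
#'
#' Automatic detection stands in for expert annotation; curated QRS marks can
#' be injected via the `manual_qrs` argument of [annotate_segments()].
#'
#' @param ecg Numeric vector, ECG in mV (raw or band-pass filtered).
#' @param sample_rate_hz Sampling rate in Hz.
#' @param refractory_s Minimum separation between detections (default 0.2 s).
#' @return Strictly increasing integer vector of fiducial sample indices
#'   (1-based); empty when no QRS is found.
#' @export
detect_qrs <- function(ecg, sample_rate_hz, refractory_s = 0.2) {
  check_numeric_series(ecg, "ecg")
  check_sample_rate(sample_rate_hz)
  n <- length(ecg)
  if (n < 0.3 * sample_rate_hz || sd(ecg) < 1e-12) {
    return(integer(0))
  }
  hf <- bandpass(ecg, sample_rate_hz, 10, min(30, sample_rate_hz / 2 - 1),
                 order = 2L, zero_phase = TRUE)
  mf <- bandpass(ecg, sample_rate_hz, 3, min(30, sample_rate_hz / 2 - 1),
                 order = 2L, zero_phase = TRUE)
  if (stats::var(mf) <= 0 || stats::var(hf) / stats::var(mf) < 0.1) {
    return(integer(0))
  }
  f <- bandpass(ecg, sample_rate_hz, 8, 20, order = 2L, zero_phase = TRUE)
  s <- c(diff(f), 0)^2
  w <- max(1L, round(0.08 * sample_rate_hz))
  mwi <- as.numeric(stats::filter(s, rep(1 / w, w), sides = 2))
  mwi[is.na(mwi)] <- 0
  peak_max <- max(mwi)
  if (peak_max <= 0) {
    return(integer(0))
  }
  thr <- max(0.25 * peak_max, 2 * median(mwi))

  is_peak <- mwi >= thr &
    mwi >= c(-Inf, mwi[-n]) &
    mwi >= c(mwi[-1], -Inf)
  cand <- which(is_peak)
  if (length(cand) == 0L) {
    return(integer(0))
  }
  # refractory: greedy by descending energy
  refr <- round(refractory_s * sample_rate_hz)
  cand <- cand[order(mwi[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand) {
    if (all(abs(i - kept) >= refr)) kept <- c(kept, i)
  }
  kept <- sort(kept)

  # fiducial refinement: centre of the biphasic deflection
  half <- as.integer(round(0.08 * sample_rate_hz))
  fid <- vapply(kept, function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    win <- f[lo:hi]
    as.integer(round(lo + (which.max(win) + which.min(win)) / 2 - 1L))
  }, integer(1))
  fid <- sort(unique(fid))
  # dedupe fiducials pulled to the same R wave
  if (length(fid) > 1L) {
    fid <- fid[c(TRUE, diff(fid) >= refr)]
  }
  as.integer(fid)
}

#' Rhythm classification of a segment
#'
#' A window is *organized* when it contains at least one QRS complex, and
#' *disorganized* otherwise.
#'
#' @param qrs Integer vector of QRS fiducial indices ([detect_qrs()] or
#'   manual marks).
#' @return `"organized"` or `"disorganized"`.
#' @export
classify_rhythm <- function(qrs) {
  if (length(qrs) >= 1L) "organized" else "disorganized"
}

#' Arterial-pressure features of a segment
#'
#' Systolic pressure is the window maximum, diastolic the minimum, pulse
#' pressure their difference, and mean arterial pressure (MAP) the arithmetic
#' mean over the window. Computed on the raw (unfiltered) ABP slice.
#'
#' @param abp Numeric vector, arterial blood pressure in mmHg.
#' @return One-row tibble with `sap_mmhg`, `dap_mmhg`,
#'   `pulse_pressure_mmhg`, `map_mmhg`.
#' @export
abp_features <- function(abp) {
  check_numeric_series(abp, "abp")
  sap <- max(abp)
  dap <- min(abp)
  tibble(sap_mmhg = sap, dap_mmhg = dap,
         pulse_pressure_mmhg = sap - dap, map_mmhg = mean(abp))
}

#' Hemodynamic classification (PR vs. PEA)
#'
#' A perfusing rhythm (PR) is an organized rhythm with systolic pressure
#' strictly above 60 mmHg and pulse pressure strictly above 10 mmHg; an
#' organized rhythm failing either criterion is pulseless electrical
#' activity (PEA). Disorganized rhythms are not hemodynamically classified.
#'
#' @param rhythm `"organized"` or `"disorganized"` (vectorized).
#' @param sap_mmhg Systolic arterial pressure in mmHg.
#' @param pulse_pressure_mmhg Pulse pressure in mmHg.
#' @return Character vector in `{"PR", "PEA", "not_applicable"}`.
#' @export
classify_hemodynamics <- function(rhythm, sap_mmhg, pulse_pressure_mmhg) {
  dplyr::case_when(
    rhythm == "disorganized" ~ "not_applicable",
    sap_mmhg > 60 & pulse_pressure_mmhg > 10 ~ "PR",
    TRUE ~ "PEA"
  )
}

#' Heart rate from QRS fiducials
#'
#' 60 divided by the median RR interval in seconds; the median is robust to a
#' single missed or spurious detection inside a short window. Undefined
#' (`NA`) with fewer than two QRS.
#'
#' @inheritParams classify_rhythm
#' @param sample_rate_hz Sampling rate in Hz.
#' @return Heart rate in beats/min, or `NA_real_`.
#' @export
heart_rate <- function(qrs, sample_rate_hz) {
  check_sample_rate(sample_rate_hz)
  if (length(qrs) < 2L) {
    return(NA_real_)
  }
  if (any(diff(qrs) <= 0)) {
    abort("QRS indices must be strictly increasing.",
          class = "ccpulse_annotation_error")
  }
  60 / (median(diff(qrs)) / sample_rate_hz)
}

#' Annotate a table of segments
#'
#' Runs the full labelling chain on a nested segment table (from
#' [extract_segments()] or [generate_dataset()]): ECG preprocessing, QRS
#' detection, rhythm classification, ABP features, PR/PEA classification and
#' heart rate. Exclusion flags (rhythm transitions, defibrillation shocks)
#' are user- or generator-supplied metadata, not detected automatically.
#'
#' @param segments Nested tibble with `segment_id` and list-columns `ecg`,
#'   `abp` (and optionally `acc`).
#' @param sample_rate_hz Sampling rate; defaults to the table's attribute.
#' @param manual_qrs Optional named list (or tibble with columns
#'   `segment_id`, `idx`) of curated QRS indices overriding the detector.
#' @param exclusions Optional tibble with columns `segment_id` and
#'   `exclusion_reason` (`"rhythm_transition"` or `"defibrillation_shock"`).
#' @return A tibble with one row per segment: `segment_id`, `rhythm`,
#'   `hemodynamic`, `excluded`, `exclusion_reason`, `sap_mmhg`,
#'   `pulse_pressure_mmhg`, `map_mmhg`, `hr_bpm`, `source`, plus a `qrs`
#'   list-column of fiducial indices.
#' @export
annotate_segments <- function(segments, sample_rate_hz = NULL,
                              manual_qrs = NULL, exclusions = NULL) {
  fs <- sample_rate_hz %||% attr(segments, "sample_rate_hz")
  check_sample_rate(fs)
  if (inherits(manual_qrs, "data.frame")) {
    manual_qrs <- split(manual_qrs$idx, manual_qrs$segment_id)
  }

  rows <- purrr::pmap(
    list(segments$segment_id, segments$ecg, segments$abp),
    function(id, ecg, abp) {
      manual <- !is.null(manual_qrs) && id %in% names(manual_qrs)
      qrs <- if (manual) {
        sort(as.integer(manual_qrs[[id]]))
      } else {
        detect_qrs(preprocess_ecg(ecg, fs), fs)
      }
      rhythm <- classify_rhythm(qrs)
      feat <- abp_features(abp)
      hemo <- if (rhythm == "organized") {
        classify_hemodynamics(rhythm, feat$sap_mmhg, feat$pulse_pressure_mmhg)
      } else {
        "not_applicable"
      }
      tibble(
        segment_id = id,
        rhythm = rhythm,
        hemodynamic = hemo,
        sap_mmhg = feat$sap_mmhg,
        pulse_pressure_mmhg = feat$pulse_pressure_mmhg,
        map_mmhg = feat$map_mmhg,
        hr_bpm = heart_rate(qrs, fs),
        source = if (manual) "manual" else "automatic",
        qrs = list(qrs)
      )
    })
  out <- dplyr::bind_rows(rows)

  out$exclusion_reason <- "none"
  if (!is.null(exclusions) && nrow(exclusions) > 0L) {
    m <- match(out$segment_id, exclusions$segment_id)
    hit <- !is.na(m)
    out$exclusion_reason[hit] <- exclusions$exclusion_reason[m[hit]]
  }
  out$excluded <- out$exclusion_reason != "none"
  dplyr::relocate(out, "excluded", "exclusion_reason", .after = "hemodynamic")
}
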