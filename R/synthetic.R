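#' Default parameters for the synthetic CPR generator
#'
#' The generator emulates the signal conditions of a porcine
#' cardiac-arrest/CPR experiment: 300 Hz multichannel sampling; 3-s
#' compression-free analysis windows; perfusing rhythm (PR) with heart rate
#' 159 +/- 51 beats/min and MAP 115.3 +/- 36.3 mmHg; pulseless electrical
#' activity (PEA) with 86 +/- 45 beats/min and 15.2 +/- 9.5 mmHg; chest
#' compressions oscillating at 46.35 +/- 15.95 m/s^2 versus pulse-synchronous
#' acceleration transients of 1.83 +/- 0.96 m/s^2; compression pauses of
#' 3--5 s. Distributions are Gaussian with those moments, clipped to
#' physiological ranges (HR to \[30, 300\] beats/min; PR MAP to
#' \[80, 250\] mmHg and PEA MAP to \[2, 40\] mmHg so that generated classes
#' stay away from the 60/10 mmHg decision boundaries). The
#' electromechanical ECG-to-acceleration delay is drawn from 50--200 ms.
#'
#' @param ... Named overrides of any default listed above.
#' @return A named list of generator parameters.
#' @export
gen_params <- function(...) {
  p <- list(
    sample_rate_hz = 300,
    duration_s = 3,
    hr_pr_bpm = c(mean = 159, sd = 51),
    hr_pea_bpm = c(mean = 86, sd = 45),
    map_pr_mmhg = c(mean = 115.3, sd = 36.3),
    map_pea_mmhg = c(mean = 15.2, sd = 9.5),
    cc_osc_amp_ms2 = c(mean = 46.35, sd = 15.95),
    pulse_osc_amp_ms2 = c(mean = 1.83, sd = 0.96),
    acc_noise_sd_ms2 = 3.5,
    ecg_noise_sd_mv = 0.05,
    abp_noise_sd_mmhg = 0.5,
    mech_delay_s = c(0.05, 0.20),
    pause_s = c(3, 5),
    compression_s = c(12, 18),
    cc_rate_hz = 2,
    qrs_sigma_s = 0.010,
    t_amp_pr_mv = 0.80,
    t_amp_pea_mv = 0.10,
    t_sigma_s = 0.05,
    t_offset_s = 0.18,
    rr_jitter = 0.05,
    wander_amp_mv = 0.1,
    wander_hz = 0.3
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad) > 0L) {
    abort(sprintf("Unknown generator parameter(s): %s",
                  paste(bad, collapse = ", ")),
          class = "ccpulse_config_error")
  }
  p[names(dots)] <- dots
  p
}

rnorm_clipped <- function(n, moments, lo, hi) {
  pmin(pmax(rnorm(n, moments[["mean"]], moments[["sd"]]), lo), hi)
}

# one full beat complex centred on the R wave: sharp biphasic QRS plus a
# broad biphasic (discordant) ST-T wave; systole spans QRS to T, so this is
# also the shape whose band-limited version drives the mechanical pulse
# transient
beat_template <- function(sample_rate_hz, qrs_sigma_s = 0.010,
                          t_amp = 0.70, t_sigma_s = 0.05,
                          t_offset_s = 0.18) {
  half_s <- max(4 * qrs_sigma_s, t_offset_s + 4 * t_sigma_s)
  t <- seq(-half_s, half_s, by = 1 / sample_rate_hz)
  dog <- function(u) -u * exp(0.5 - u^2 / 2)
  dog(t / qrs_sigma_s) + t_amp * dog((t - t_offset_s) / t_sigma_s)
}

add_kernel <- function(x, kernel, center_idx) {
  n <- length(x)
  half <- (length(kernel) - 1L) %/% 2L
  lo <- center_idx - half
  hi <- lo + length(kernel) - 1L
  ks <- max(1L, lo)
  ke <- min(n, hi)
  if (ks > ke) return(x)
  x[ks:ke] <- x[ks:ke] + kernel[(ks - lo + 1L):(ke - lo + 1L)]
  x
}

#' Synthetic ECG window
#'
#' Organized rhythms are a train of beat complexes -- a sharp biphasic QRS
#' (derivative of a Gaussian, unit peak in mV, width parameter
#' `qrs_sigma_s`) followed by a smooth T wave -- at the requested rate with
#' +/-5 per cent RR jitter, riding on 0.3 Hz baseline wander plus white
#' Gaussian noise. Disorganized (VF-like) rhythms are a band-limited
#' 3--8 Hz Gaussian process with no repeating template and, in particular,
#' none of the high-frequency content a QRS deflection carries. Ground-truth
#' QRS times (R-wave centres) are returned alongside.
#'
#' @param rhythm `"organized"` or `"disorganized"`.
#' @param hr_bpm Heart rate in beats/min (organized only).
#' @param duration_s Window length in seconds.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param noise_sd Additive white noise SD in mV.
#' @param qrs_sigma_s Width parameter of the QRS template in seconds (the
#'   two lobes of the biphasic wave are `2 * sigma` apart).
#' @param t_amp T-wave amplitude in mV relative to the unit R wave.
#' @param t_sigma_s,t_offset_s T-wave width and R-to-T delay in seconds.
#' @param rr_jitter Relative uniform jitter of each RR interval.
#' @param wander_amp_mv,wander_hz Baseline wander amplitude and frequency.
#' @param seed Optional integer; when given, the draw is made under a local
#'   RNG seed without disturbing the caller's stream.
#' @return List with `ecg` (numeric vector) and `qrs_times` (seconds).
#' @export
gen_ecg <- function(rhythm = c("organized", "disorganized"), hr_bpm = 120,
                    duration_s = 3, sample_rate_hz = 300, noise_sd = 0.05,
                    qrs_sigma_s = 0.010, t_amp = 0.70, t_sigma_s = 0.05,
                    t_offset_s = 0.18, rr_jitter = 0.05,
                    wander_amp_mv = 0.1, wander_hz = 0.3, seed = NULL) {
  rhythm <- match.arg(rhythm)
  check_sample_rate(sample_rate_hz)
  with_opt_seed(seed, {
    n <- round(duration_s * sample_rate_hz)
    t <- seq_len(n) / sample_rate_hz
    wander <- wander_amp_mv * sin(2 * pi * wander_hz * t + runif(1, 0, 2 * pi))
    if (rhythm == "disorganized") {
      raw <- rnorm(n + 200)
      vf <- bandpass(raw, sample_rate_hz, 3, 8, order = 2L)[101:(100 + n)]
      vf <- vf / max(sd(vf), 1e-12) * 0.3
      return(list(ecg = vf + wander + rnorm(n, 0, noise_sd),
                  qrs_times = numeric(0)))
    }
    rr <- 60 / hr_bpm
    times <- runif(1, 0.1, min(0.3, rr / 2))
    repeat {
      nxt <- times[length(times)] + rr * (1 + rr_jitter * runif(1, -1, 1))
      if (nxt > duration_s - 2 * qrs_sigma_s) break
      times <- c(times, nxt)
    }
    ecg <- numeric(n)
    tmpl <- beat_template(sample_rate_hz, qrs_sigma_s, t_amp, t_sigma_s,
                          t_offset_s)
    for (tt in times) {
      ecg <- add_kernel(ecg, tmpl, round(tt * sample_rate_hz))
    }
    list(ecg = ecg + wander + rnorm(n, 0, noise_sd), qrs_times = times)
  })
}

#' Synthetic arterial-pressure window
#'
#' PR windows carry one pressure pulse per heart beat -- a fast systolic
#' upstroke followed by an exponential diastolic decay -- delayed
#' 100--200 ms after the QRS and scaled so that systolic pressure exceeds
#' 60 mmHg and pulse pressure exceeds 10 mmHg, with the window mean matching
#' `map_target_mmhg`. PEA windows drift slowly around the (low) target MAP
#' with pulse pressure held below 10 mmHg. Ground-truth features of the
#' noise-free trace are returned.
#'
#' @param hemo_class `"PR"` or `"PEA"`.
#' @param qrs_times QRS times in seconds (required for PR).
#' @param map_target_mmhg Target mean arterial pressure in mmHg.
#' @inheritParams gen_ecg
#' @param noise_sd Additive measurement noise SD in mmHg.
#' @return List with `abp` and ground-truth `sap_mmhg`,
#'   `pulse_pressure_mmhg`, `map_mmhg`.
#' @export
gen_abp <- function(hemo_class = c("PR", "PEA"), qrs_times = numeric(0),
                    map_target_mmhg = 115, duration_s = 3,
                    sample_rate_hz = 300, noise_sd = 0.5, seed = NULL) {
  hemo_class <- match.arg(hemo_class)
  check_sample_rate(sample_rate_hz)
  with_opt_seed(seed, {
    n <- round(duration_s * sample_rate_hz)
    t <- seq_len(n) / sample_rate_hz
    if (hemo_class == "PR") {
      if (length(qrs_times) == 0L) {
        abort("PR pressure generation needs `qrs_times`.",
              class = "ccpulse_config_error")
      }
      delay <- runif(1, 0.10, 0.20)
      rise <- 0.08
      tau <- 0.25
      kernel_t <- seq(0, 1, by = 1 / sample_rate_hz)
      kernel <- ifelse(kernel_t <= rise,
                       sin(pi * kernel_t / (2 * rise)),
                       exp(-(kernel_t - rise) / tau))
      pulse <- numeric(n)
      for (tt in qrs_times + delay) {
        i0 <- round(tt * sample_rate_hz)
        if (i0 > n) next
        idx <- i0:min(n, i0 + length(kernel) - 1L)
        pulse[idx] <- pmax(pulse[idx], kernel[seq_along(idx)])
      }
      pp <- max(30, 0.4 * map_target_mmhg)
      dap <- map_target_mmhg - pp * mean(pulse)
      clean <- dap + pp * pulse
    } else {
      drift <- runif(1, 1, 2) *
        sin(2 * pi * runif(1, 0.1, 0.3) * t + runif(1, 0, 2 * pi))
      bump <- numeric(n)
      if (length(qrs_times) > 0L) {
        bk_t <- seq(0, 0.4, by = 1 / sample_rate_hz)
        bk <- runif(1, 0.5, 1.5) * sin(pi * bk_t / 0.4)^2
        for (tt in qrs_times + 0.15) {
          bump <- add_kernel(bump, bk, round(tt * sample_rate_hz))
        }
      }
      clean <- map_target_mmhg + drift - mean(drift) + bump - mean(bump)
      clean <- pmax(clean, 0)
    }
    list(abp = clean + rnorm(n, 0, noise_sd),
         sap_mmhg = max(clean),
         pulse_pressure_mmhg = max(clean) - min(clean),
         map_mmhg = mean(clean))
  })
}

# pulse-synchronous mechanical transient: the QRS-T contraction complex
# band-limited to the accelerometer analysis band, i.e. a damped oscillation
# confined to 0.5-7.5 Hz, normalized to unit peak; trimmed to its support
# but kept length-symmetric around the R-wave centre so that kernel
# placement preserves the ECG-to-ACC delay
acc_pulse_kernel <- function(sample_rate_hz, qrs_sigma_s = 0.010,
                             t_amp = 0.70, t_sigma_s = 0.05,
                             t_offset_s = 0.16) {
  tmpl <- beat_template(sample_rate_hz, qrs_sigma_s, t_amp, t_sigma_s,
                        t_offset_s)
  pad <- 2 * sample_rate_hz
  k <- bandpass(c(numeric(pad), tmpl, numeric(pad)), sample_rate_hz,
                0.5, 7.5, order = 4L)
  centre <- pad + (length(tmpl) + 1L) %/% 2L
  keep <- which(abs(k) > 1e-4 * max(abs(k)))
  half <- max(abs(range(keep) - centre))
  lo <- max(1L, centre - half)
  hi <- min(length(k), centre + half)
  k <- k[lo:hi]
  k / max(abs(k))
}

#' Synthetic chest-acceleration window
#'
#' Background Gaussian sensor noise everywhere; a strong oscillation at the
#' compression rate (default 2 Hz) inside compression intervals; and, for PR
#' only, a pulse-synchronous damped oscillatory transient (the contraction
#' impulse band-limited to 0.5--7.5 Hz) after each QRS at the mechanical
#' delay, with the requested peak amplitude, inside pauses.
#'
#' @param hemo_class `"PR"` or `"PEA"`.
#' @param qrs_times QRS times in seconds.
#' @param schedule Optional tibble with columns `start_s`, `end_s`, `type`
#'   (`"compression"`/`"pause"`); `NULL` treats the whole window as a pause.
#' @param pulse_amp_ms2 Peak amplitude of the pulse transient (m/s^2).
#' @param cc_amp_ms2 Amplitude of the compression oscillation (m/s^2).
#' @param noise_sd Background noise SD in m/s^2.
#' @param mech_delay_s ECG-to-acceleration mechanical delay in seconds.
#' @param cc_rate_hz Chest-compression rate in Hz (default 2, i.e.
#'   120/min).
#' @inheritParams gen_ecg
#' @return List with `acc`, `mech_delay_s` and the `schedule` used.
#' @export
gen_acc <- function(hemo_class = c("PR", "PEA"), qrs_times = numeric(0),
                    schedule = NULL, pulse_amp_ms2 = 1.83,
                    cc_amp_ms2 = 46.35, noise_sd = 3.5,
                    mech_delay_s = 0.12, duration_s = 3,
                    sample_rate_hz = 300, qrs_sigma_s = 0.010,
                    t_amp = 0.70, t_sigma_s = 0.05, t_offset_s = 0.18,
                    cc_rate_hz = 2, seed = NULL) {
  hemo_class <- match.arg(hemo_class)
  check_sample_rate(sample_rate_hz)
  with_opt_seed(seed, {
    n <- round(duration_s * sample_rate_hz)
    t <- seq_len(n) / sample_rate_hz
    if (is.null(schedule)) {
      schedule <- tibble(start_s = 0, end_s = duration_s, type = "pause")
    }
    acc <- rnorm(n, 0, noise_sd)
    for (i in seq_len(nrow(schedule))) {
      if (schedule$type[i] != "compression") next
      idx <- which(t > schedule$start_s[i] & t <= schedule$end_s[i])
      acc[idx] <- acc[idx] +
        cc_amp_ms2 * sin(2 * pi * cc_rate_hz * t[idx] + runif(1, 0, 2 * pi))
    }
    if (hemo_class == "PR" && length(qrs_times) > 0L) {
      kernel <- acc_pulse_kernel(sample_rate_hz, qrs_sigma_s, t_amp,
                                 t_sigma_s, t_offset_s)
      in_pause <- rep(FALSE, n)
      for (i in seq_len(nrow(schedule))) {
        if (schedule$type[i] == "pause") {
          in_pause[t > schedule$start_s[i] & t <= schedule$end_s[i]] <- TRUE
        }
      }
      pulse <- numeric(n)
      for (tt in qrs_times + mech_delay_s) {
        pulse <- add_kernel(pulse, pulse_amp_ms2 * kernel,
                            round(tt * sample_rate_hz))
      }
      acc <- acc + pulse * in_pause
    }
    list(acc = acc, mech_delay_s = mech_delay_s, schedule = schedule)
  })
}

gen_one_segment <- function(label, params) {
  fs <- params$sample_rate_hz
  hr <- if (label == "PR") {
    rnorm_clipped(1, params$hr_pr_bpm, 30, 300)
  } else {
    rnorm_clipped(1, params$hr_pea_bpm, 30, 300)
  }
  map_target <- if (label == "PR") {
    rnorm_clipped(1, params$map_pr_mmhg, 80, 250)
  } else {
    rnorm_clipped(1, params$map_pea_mmhg, 2, 40)
  }
  t_amp <- if (label == "PR") params$t_amp_pr_mv else params$t_amp_pea_mv
  delay <- runif(1, params$mech_delay_s[1], params$mech_delay_s[2])
  pulse_amp <- rnorm_clipped(1, params$pulse_osc_amp_ms2, 0.3, Inf)

  e <- gen_ecg("organized", hr_bpm = hr, duration_s = params$duration_s,
               sample_rate_hz = fs, noise_sd = params$ecg_noise_sd_mv,
               qrs_sigma_s = params$qrs_sigma_s, t_amp = t_amp,
               t_sigma_s = params$t_sigma_s, t_offset_s = params$t_offset_s,
               rr_jitter = params$rr_jitter,
               wander_amp_mv = params$wander_amp_mv,
               wander_hz = params$wander_hz)
  a <- gen_abp(label, e$qrs_times, map_target_mmhg = map_target,
               duration_s = params$duration_s, sample_rate_hz = fs,
               noise_sd = params$abp_noise_sd_mmhg)
  g <- gen_acc(label, e$qrs_times, pulse_amp_ms2 = pulse_amp,
               cc_amp_ms2 = rnorm_clipped(1, params$cc_osc_amp_ms2, 10, Inf),
               noise_sd = params$acc_noise_sd_ms2, mech_delay_s = delay,
               duration_s = params$duration_s, sample_rate_hz = fs,
               qrs_sigma_s = params$qrs_sigma_s, t_amp = params$t_amp_pr_mv,
               t_sigma_s = params$t_sigma_s, t_offset_s = params$t_offset_s,
               cc_rate_hz = params$cc_rate_hz)

  tibble(label = label,
         hr_true_bpm = hr,
         sap_true_mmhg = a$sap_mmhg,
         pulse_pressure_true_mmhg = a$pulse_pressure_mmhg,
         map_true_mmhg = a$map_mmhg,
         mech_delay_true_s = delay,
         pulse_amp_true_ms2 = pulse_amp,
         qrs_times_true = list(e$qrs_times),
         ecg = list(e$ecg), abp = list(a$abp), acc = list(g$acc))
}

#' Generate a labelled synthetic segment dataset
#'
#' Draws independent compression-free 3-s windows with per-segment ground
#' truth, reproducible from `(params, seed)`. Segments are grouped into
#' synthetic "animals" so that animal-level train/test splitting (all of an
#' animal's segments in one split) can be exercised: PR segments come from
#' many animals with few segments each, PEA segments from few animals with
#' many each, mirroring the skew of arrest experiments.
#'
#' @param n_pr,n_pea Number of PR and PEA segments.
#' @param params Generator parameters from [gen_params()].
#' @param seed Optional integer seed.
#' @return A nested tibble with one row per segment: `segment_id`,
#'   `animal_id`, `label`, ground-truth columns (`hr_true_bpm`,
#'   `sap_true_mmhg`, `pulse_pressure_true_mmhg`, `map_true_mmhg`,
#'   `mech_delay_true_s`, `pulse_amp_true_ms2`, `qrs_times_true`) and
#'   list-columns `ecg`, `abp`, `acc`. Attributes `sample_rate_hz` and
#'   `params` are set.
#' @examples
#' ds <- generate_dataset(3, 5, seed = 1)
#' dplyr::count(ds, label)
#' @export
generate_dataset <- function(n_pr, n_pea, params = gen_params(), seed = NULL) {
  if (n_pr < 0 || n_pea < 0) {
    abort("`n_pr` and `n_pea` must be non-negative.",
          class = "ccpulse_config_error")
  }
  with_opt_seed(seed, {
    labels <- c(rep("PR", n_pr), rep("PEA", n_pea))
    pr_animals <- if (n_pr > 0) paste0("pr_animal_", seq_len(max(1, ceiling(n_pr / 1.5)))) else character(0)
    pea_animals <- if (n_pea > 0) paste0("pea_animal_", seq_len(max(1, ceiling(n_pea / 10)))) else character(0)
    animal <- c(
      if (n_pr > 0) sort(rep_len(pr_animals, n_pr)),
      if (n_pea > 0) sort(rep_len(pea_animals, n_pea)))
    rows <- purrr::map(labels, gen_one_segment, params = params)
    out <- dplyr::bind_rows(rows)
    out <- dplyr::bind_cols(
      tibble(segment_id = sprintf("syn_seg%04d", seq_along(labels)),
             animal_id = animal),
      out)
    attr(out, "sample_rate_hz") <- params$sample_rate_hz
    attr(out, "params") <- params
    out
  })
}

#' Animal-grouped train/test split
#'
#' Assigns whole animals to the training or testing split (every segment of
#' an animal lands in the same split), greedily balancing the per-class
#' segment counts toward `prop_training`.
#'
#' @param dataset Dataset from [generate_dataset()] (needs `animal_id` and
#'   `label` columns).
#' @param prop_training Target fraction of each class's segments in the
#'   training split (default 0.5).
#' @param seed Optional integer seed for the animal shuffle.
#' @return `dataset` with a `set` column (`"training"`/`"testing"`) added.
#' @export
split_dataset <- function(dataset, prop_training = 0.5, seed = NULL) {
  with_opt_seed(seed, {
    dataset$set <- NA_character_
    for (lab in unique(dataset$label)) {
      rows <- which(dataset$label == lab)
      animals <- sample(unique(dataset$animal_id[rows]))
      target <- prop_training * length(rows)
      assigned <- 0L
      for (an in animals) {
        an_rows <- rows[dataset$animal_id[rows] == an]
        if (assigned < target) {
          dataset$set[an_rows] <- "training"
          assigned <- assigned + length(an_rows)
        } else {
          dataset$set[an_rows] <- "testing"
        }
      }
    }
    dataset
  })
}

#' Generate a full synthetic CPR recording
#'
#' Builds a continuous multichannel recording alternating chest-compression
#' bursts with 3--5 s pauses, for exercising pause detection and segment
#' extraction end to end. The underlying rhythm is organized throughout with
#' the hemodynamic class fixed for the whole recording.
#'
#' @param label `"PR"` or `"PEA"`.
#' @param n_pauses Number of compression pauses (default 3).
#' @param params Generator parameters from [gen_params()].
#' @param seed Optional integer seed.
#' @param record_id Label for the recording.
#' @return A recording tibble (`time_s`, `ecg_mv`, `abp_mmhg`, `acc_ms2`)
#'   with attributes `sample_rate_hz`, `record_id` and `truth` (a list with
#'   the compression/pause `schedule` and the generating draws).
#' @export
gen_recording <- function(label = c("PR", "PEA"), n_pauses = 3,
                          params = gen_params(), seed = NULL,
                          record_id = "synthetic_record") {
  label <- match.arg(label)
  with_opt_seed(seed, {
    fs <- params$sample_rate_hz
    # schedule: compression / pause alternation, compressions first and last
    segs <- list()
    t_cur <- 0
    for (i in seq_len(n_pauses)) {
      cdur <- runif(1, params$compression_s[1], params$compression_s[2])
      segs[[length(segs) + 1L]] <- tibble(start_s = t_cur, end_s = t_cur + cdur,
                                          type = "compression")
      t_cur <- t_cur + cdur
      pdur <- runif(1, params$pause_s[1], params$pause_s[2])
      segs[[length(segs) + 1L]] <- tibble(start_s = t_cur, end_s = t_cur + pdur,
                                          type = "pause")
      t_cur <- t_cur + pdur
    }
    cdur <- runif(1, params$compression_s[1], params$compression_s[2])
    segs[[length(segs) + 1L]] <- tibble(start_s = t_cur, end_s = t_cur + cdur,
                                        type = "compression")
    t_cur <- t_cur + cdur
    schedule <- dplyr::bind_rows(segs)
    duration <- t_cur

    hr <- if (label == "PR") {
      rnorm_clipped(1, params$hr_pr_bpm, 30, 300)
    } else {
      rnorm_clipped(1, params$hr_pea_bpm, 30, 300)
    }
    map_target <- if (label == "PR") {
      rnorm_clipped(1, params$map_pr_mmhg, 80, 250)
    } else {
      rnorm_clipped(1, params$map_pea_mmhg, 2, 40)
    }
    t_amp <- if (label == "PR") params$t_amp_pr_mv else params$t_amp_pea_mv
    delay <- runif(1, params$mech_delay_s[1], params$mech_delay_s[2])
    pulse_amp <- rnorm_clipped(1, params$pulse_osc_amp_ms2, 0.3, Inf)

    e <- gen_ecg("organized", hr_bpm = hr, duration_s = duration,
                 sample_rate_hz = fs, noise_sd = params$ecg_noise_sd_mv,
                 qrs_sigma_s = params$qrs_sigma_s, t_amp = t_amp,
                 t_sigma_s = params$t_sigma_s, t_offset_s = params$t_offset_s,
                 rr_jitter = params$rr_jitter,
                 wander_amp_mv = params$wander_amp_mv,
                 wander_hz = params$wander_hz)
    a <- gen_abp(label, e$qrs_times, map_target_mmhg = map_target,
                 duration_s = duration, sample_rate_hz = fs,
                 noise_sd = params$abp_noise_sd_mmhg)
    g <- gen_acc(label, e$qrs_times, schedule = schedule,
                 pulse_amp_ms2 = pulse_amp,
                 cc_amp_ms2 = rnorm_clipped(1, params$cc_osc_amp_ms2, 10, Inf),
                 noise_sd = params$acc_noise_sd_ms2, mech_delay_s = delay,
                 duration_s = duration, sample_rate_hz = fs,
                 qrs_sigma_s = params$qrs_sigma_s, t_amp = params$t_amp_pr_mv,
                 t_sigma_s = params$t_sigma_s, t_offset_s = params$t_offset_s,
                 cc_rate_hz = params$cc_rate_hz)

    n <- length(e$ecg)
    rec <- tibble(time_s = seq_len(n) / fs,
                  ecg_mv = e$ecg,
                  abp_mmhg = a$abp[seq_len(n)],
                  acc_ms2 = g$acc[seq_len(n)])
    structure(rec,
              sample_rate_hz = fs,
              record_id = record_id,
              truth = list(schedule = schedule, label = label,
                           hr_bpm = hr, map_mmhg = a$map_mmhg,
                           mech_delay_s = delay, pulse_amp_ms2 = pulse_amp,
                           qrs_times = e$qrs_times),
              class = c("cpr_recording", class(rec)))
  })
}

#' Feature table of a synthetic dataset
#'
#' Convenience wrapper: annotates a (split) synthetic dataset, scores every
#' segment with [detect_pulses()] and returns the per-segment feature table
#' consumed by [evaluate_study()] (columns `segment_id`, `set`, `label`,
#' `map_mmhg`, `ccp`, `hr_bpm`).
#'
#' @param dataset Dataset from [generate_dataset()], after [split_dataset()]
#'   (a `set` column is required for downstream evaluation).
#' @param annotations Optional precomputed [annotate_segments()] output.
#' @return A feature-table tibble.
#' @export
study_feature_table <- function(dataset, annotations = NULL) {
  ann <- annotations %||% annotate_segments(dataset)
  det <- detect_pulses(dataset)
  out <- tibble(segment_id = dataset$segment_id,
                set = if ("set" %in% names(dataset)) dataset$set else NA_character_,
                label = dataset$label)
  out <- left_join(out, dplyr::select(ann, "segment_id", "map_mmhg", "hr_bpm"),
                   by = "segment_id")
  left_join(out, dplyr::select(det, "segment_id", "ccp"), by = "segment_id")
}
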