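fs <- 300

test_that("normalized cross-correlation matches the direct-sum oracle", {
  set.seed(19)
  for (n in c(2, 3, 5, 17, 64, 256)) {
    x <- rnorm(n)
    y <- rnorm(n)
    cc <- normalized_xcorr(x, y)
    want <- direct_xcorr(x, y)
    expect_equal(cc$lag, want$lag)
    expect_lt(max(abs(cc$value - want$value)), 1e-10)
    expect_true(all(abs(cc$value) <= 1 + 1e-12))   # Cauchy-Schwarz bound
  }

  # hand-checkable impulse pair: full match at lag -1
  cc <- normalized_xcorr(c(1, 0, 0), c(0, 1, 0))
  expect_equal(cc$value[cc$lag == -1], 1)
  expect_equal(cc$value[cc$lag == 0], 0)

  # energy_product mode reproduces the direct sum under that normalization
  x <- rnorm(32); y <- rnorm(32)
  ccp2 <- normalized_xcorr(x, y, normalization = "energy_product")
  expect_lt(max(abs(ccp2$value -
                      direct_xcorr(x, y, "energy_product")$value)), 1e-10)
})

test_that("cross-correlation symmetry and degenerate inputs", {
  set.seed(23)
  x <- rnorm(40); y <- rnorm(40)
  ab <- normalized_xcorr(x, y)
  ba <- normalized_xcorr(y, x)
  expect_equal(ab$value, rev(ba$value), tolerance = 1e-12)  # r_xy(l) = r_yx(-l)

  expect_error(normalized_xcorr(x, y[1:10]), class = "ccpulse_shape_error")
  expect_error(normalized_xcorr(rep(0, 40), y),
               class = "ccpulse_degenerate_input_error")
  expect_error(normalized_xcorr(x, rep(0, 40)),
               class = "ccpulse_degenerate_input_error")
})

test_that("peak extraction returns the signed maximum with deterministic ties", {
  set.seed(29)
  x <- rnorm(100)
  pk <- peak_correlation(normalized_xcorr(x, x))
  expect_equal(pk$ccp, 1, tolerance = 1e-12)
  expect_equal(pk$peak_lag, 0L)

  cc <- tibble::tibble(lag = -6:6, value = c(0.1, 0.701, rep(0, 9), 0.701, 0.2))
  expect_equal(peak_correlation(cc)$ccp, 0.701)
  expect_equal(peak_correlation(cc)$peak_lag, -5L)  # tie toward negative lag

  # smaller absolute lag wins before the sign rule applies
  cc2 <- tibble::tibble(lag = -6:6, value = c(0.9, rep(0, 8), 0.9, 0, 0, 0.3))
  expect_equal(peak_correlation(cc2)$peak_lag, 3L)
})

test_that("scale and sign behaviour of the segment statistic", {
  set.seed(31)
  e <- gen_ecg("organized", hr_bpm = 110, sample_rate_hz = fs)
  a <- gen_acc("PR", e$qrs_times, mech_delay_s = 0.12, sample_rate_hz = fs)

  base <- ccp_for_segment(e$ecg, a$acc, fs)
  scaled <- ccp_for_segment(5.7 * e$ecg, 0.02 * a$acc, fs)
  expect_equal(base$ccp, scaled$ccp, tolerance = 1e-5)
  expect_equal(base$peak_lag, scaled$peak_lag)

  flipped <- normalized_xcorr(e$ecg, -a$acc)
  expect_equal(flipped$value, -normalized_xcorr(e$ecg, a$acc)$value,
               tolerance = 1e-12)

  # ACC equal to a scaled copy of the filtered ECG is a perfect match
  x <- preprocess_ecg(e$ecg, fs)
  r <- peak_correlation(normalized_xcorr(x, 0.25 * x))
  expect_equal(r$ccp, 1, tolerance = 1e-12)
  expect_equal(r$peak_lag, 0L)
})

test_that("segment statistic separates PR from PEA signal structure", {
  set.seed(37)
  # favourable PR: pulse locked to QRS at twice the in-band noise amplitude
  amp <- 1.83
  noise <- amp / 2 / sqrt(7 / 150)  # in-band RMS = amp / 2
  e <- gen_ecg("organized", hr_bpm = 110, sample_rate_hz = fs)
  a <- gen_acc("PR", e$qrs_times, pulse_amp_ms2 = amp, noise_sd = noise,
               mech_delay_s = 0.15, sample_rate_hz = fs)
  expect_gte(ccp_for_segment(e$ecg, a$acc, fs)$ccp, 0.3)

  # PEA: acceleration is background noise only
  ccps <- replicate(25, {
    e <- gen_ecg("organized", hr_bpm = 90, t_amp = 0.10, sample_rate_hz = fs)
    a <- gen_acc("PEA", e$qrs_times, sample_rate_hz = fs)
    ccp_for_segment(e$ecg, a$acc, fs)$ccp
  })
  expect_lt(median(ccps), 0.2)
  expect_lt(max(ccps), 0.3)
})

test_that("noise monotonically degrades the median statistic", {
  set.seed(41)
  med <- vapply(c(0.5, 2, 4, 8, 16), function(ns) {
    median(replicate(15, {
      e <- gen_ecg("organized", hr_bpm = 120, sample_rate_hz = fs)
      a <- gen_acc("PR", e$qrs_times, pulse_amp_ms2 = 1.83, noise_sd = ns,
                   mech_delay_s = 0.12, sample_rate_hz = fs)
      ccp_for_segment(e$ecg, a$acc, fs)$ccp
    }))
  }, numeric(1))
  expect_true(all(diff(med) <= 0.02))  # non-increasing up to Monte-Carlo slack
})

test_that("pulse decision uses a strict threshold", {
  base <- tibble::tibble(segment_id = "s1", ccp = 0.701, peak_lag = -30L)
  expect_equal(detect_pulse(base, 0.22)$decision, "pulse_present")
  base$ccp <- 0.048
  expect_equal(detect_pulse(base, 0.22)$decision, "pulse_absent")
  base$ccp <- 0.22
  expect_equal(detect_pulse(base, 0.22)$decision, "pulse_absent")
  expect_equal(detect_pulse(base, 0.22)$threshold_used, 0.22)
})

test_that("threshold optimization scans midpoints and breaks ties sensibly", {
  m <- optimize_threshold(c(0.1, 0.2, 0.8, 0.9), c("PEA", "PEA", "PR", "PR"))
  expect_equal(m$threshold, 0.5)
  expect_equal(m$training_accuracy, 1)
  expect_s3_class(m, "threshold_model")

  # perfectly interleaved values cannot beat the majority class
  m2 <- optimize_threshold(c(1, 2, 3, 4, 5, 6),
                           c("PR", "PEA", "PR", "PEA", "PR", "PEA"))
  expect_equal(m2$training_accuracy, 0.5)

  # accuracy ties break toward higher sensitivity (lower threshold here)
  m3 <- optimize_threshold(c(1, 2, 3, 4), c("PEA", "PR", "PEA", "PR"))
  cand_acc <- function(thr) mean((c(1, 2, 3, 4) > thr) ==
                                   c(FALSE, TRUE, FALSE, TRUE))
  expect_gte(m3$training_sensitivity, 0.5)
  expect_equal(m3$training_accuracy, cand_acc(m3$threshold))

  expect_error(optimize_threshold(c(1, 2), c("PR", "PR")),
               class = "ccpulse_degenerate_training_error")

  td <- tidy(m)
  expect_equal(td$threshold, 0.5)
  expect_equal(glance(m)$n_pr, 2L)
})

test_that("detect_pulses maps the statistic over a nested segment table", {
  ds <- generate_dataset(3, 3, seed = 4)
  det <- detect_pulses(ds, threshold = 0.22)
  expect_equal(nrow(det), 6L)
  expect_true(all(c("segment_id", "ccp", "peak_lag", "decision") %in% names(det)))
  expect_equal(det$decision, ifelse(det$ccp > 0.22, "pulse_present", "pulse_absent"))
})
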