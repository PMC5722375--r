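fs <- 300

test_that("generation is deterministic given a seed", {
  a <- gen_ecg("organized", hr_bpm = 140, seed = 123)
  b <- gen_ecg("organized", hr_bpm = 140, seed = 123)
  expect_identical(a, b)

  d1 <- generate_dataset(4, 6, seed = 99)
  d2 <- generate_dataset(4, 6, seed = 99)
  expect_identical(d1$ecg, d2$ecg)
  expect_identical(d1$abp, d2$abp)
  expect_identical(d1$acc, d2$acc)
  expect_identical(d1$hr_true_bpm, d2$hr_true_bpm)

  r1 <- gen_recording("PR", n_pauses = 2, seed = 5)
  r2 <- gen_recording("PR", n_pauses = 2, seed = 5)
  expect_identical(r1$acc_ms2, r2$acc_ms2)
})

test_that("ECG generator emits the requested rhythm structure", {
  e <- gen_ecg("organized", hr_bpm = 120, duration_s = 3, seed = 7)
  expect_length(e$ecg, 900)
  expect_length(e$qrs_times, 6)

  vf <- gen_ecg("disorganized", seed = 7)
  expect_length(vf$qrs_times, 0)
  # VF energy is band-limited: little content above 10 Hz
  spec <- Mod(fft(vf$ecg - mean(vf$ecg)))^2
  freq <- (seq_along(spec) - 1) * fs / length(spec)
  half <- freq <= fs / 2
  expect_lt(sum(spec[half & freq > 10]) / sum(spec[half]), 0.05)
})

test_that("ABP generator respects the hemodynamic class definitions", {
  set.seed(83)
  for (i in 1:10) {
    e <- gen_ecg("organized", hr_bpm = runif(1, 60, 200))
    pr <- gen_abp("PR", e$qrs_times, map_target_mmhg = runif(1, 80, 180))
    expect_gt(pr$sap_mmhg, 60)
    expect_gt(pr$pulse_pressure_mmhg, 10)

    pea <- gen_abp("PEA", e$qrs_times, map_target_mmhg = runif(1, 5, 35))
    expect_lte(pea$pulse_pressure_mmhg, 10)
    got <- classify_hemodynamics("organized", pea$sap_mmhg,
                                 pea$pulse_pressure_mmhg)
    expect_equal(got, "PEA")
  }
})

test_that("ACC generator separates compression and pause regimes", {
  set.seed(89)
  sched <- tibble::tibble(start_s = c(0, 4, 8), end_s = c(4, 8, 12),
                          type = c("compression", "pause", "compression"))
  e <- gen_ecg("organized", hr_bpm = 100, duration_s = 12)
  g <- gen_acc("PEA", e$qrs_times, schedule = sched, duration_s = 12)
  # half a compression cycle of smoothing for regime comparison
  env <- acc_envelope(g$acc, fs, window_s = 0.25)
  t <- seq_along(env) / fs
  expect_true(all(env[t > 4.3 & t < 7.7] < 10))
  expect_true(all(env[t > 0.5 & t < 3.5] > 20))
  expect_true(all(env[t > 8.5 & t < 11.5] > 20))

  # PR pause with no noise: near-perfect correlation at the mechanical delay
  g2 <- gen_acc("PR", e$qrs_times, pulse_amp_ms2 = 1.83, noise_sd = 0,
                mech_delay_s = 0.12, duration_s = 12)
  seg <- 1200 + seq_len(900)
  r <- ccp_for_segment(e$ecg[seg], g2$acc[seg], fs)
  expect_gte(r$ccp, 0.8)
  expect_lt(abs(-r$peak_lag / fs - 0.12), 0.02)
})

test_that("dataset construction yields the requested classes and grouping", {
  ds <- generate_dataset(0, 5, seed = 2)
  expect_equal(nrow(ds), 5)
  expect_true(all(ds$label == "PEA"))

  ds2 <- generate_dataset(12, 30, seed = 3)
  expect_equal(sum(ds2$label == "PR"), 12)
  expect_equal(sum(ds2$label == "PEA"), 30)
  expect_true(all(lengths(ds2$ecg) == 900))
  # PR animals hold few segments each, PEA animals many
  per_animal <- table(ds2$animal_id, ds2$label)
  expect_true(all(rowSums(per_animal) > 0))
  expect_gt(length(unique(ds2$animal_id[ds2$label == "PR"])),
            length(unique(ds2$animal_id[ds2$label == "PEA"])))
})

test_that("animal-grouped splits never tear an animal apart", {
  ds <- generate_dataset(12, 30, seed = 13)
  ds <- split_dataset(ds, prop_training = 0.5, seed = 1)
  expect_true(all(ds$set %in% c("training", "testing")))
  per_animal <- tapply(ds$set, ds$animal_id, function(s) length(unique(s)))
  expect_true(all(per_animal == 1))
  # both classes present in both splits
  tab <- table(ds$set, ds$label)
  expect_true(all(tab > 0))
})

test_that("generated class statistics sit near the study-scale moments", {
  ds <- generate_dataset(63, 153, seed = 55)
  det <- detect_pulses(ds)
  pr <- det$ccp[ds$label == "PR"]
  pea <- det$ccp[ds$label == "PEA"]
  # group means within two reference SDs of the reference means
  expect_lt(abs(mean(pr) - 0.440), 2 * 0.176)
  expect_lt(abs(mean(pea) - 0.067), 2 * 0.042)
  expect_gt(mean(pr), mean(pea))
  # MAP and HR moments propagate from their generating distributions
  expect_lt(abs(mean(ds$map_true_mmhg[ds$label == "PR"]) - 115.3), 15)
  expect_lt(abs(mean(ds$map_true_mmhg[ds$label == "PEA"]) - 15.2), 5)
  expect_lt(abs(mean(ds$hr_true_bpm[ds$label == "PR"]) - 159), 20)
})

test_that("synthetic recordings expose their ground truth for segmentation", {
  rec <- gen_recording("PEA", n_pauses = 3, seed = 17)
  truth <- attr(rec, "truth")
  expect_equal(nrow(truth$schedule[truth$schedule$type == "pause", ]), 3)
  expect_equal(recording_sample_rate(rec), fs)
  expect_true(all(c("time_s", "ecg_mv", "abp_mmhg", "acc_ms2") %in% names(rec)))
  # pauses in the schedule respect the configured 3-5 s range
  p <- truth$schedule[truth$schedule$type == "pause", ]
  expect_true(all(p$end_s - p$start_s >= 3 & p$end_s - p$start_s <= 5))
})
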