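#' Default end-to-end pipeline configuration
#'
#' One flat list holding every tunable of the processing chain, with the
#' study settings as defaults: ECG band 0.2--45 Hz and acceleration band
#' 0.5--7.5 Hz (4th-order Butterworth, zero-phase), 3-s segments anchored at
#' pause onset, envelope pause detection at 10 m/s^2, CCp decision threshold
#' 0.22, plus the synthetic-generator parameters and a seed.
#'
#' @param ... Named overrides of any top-level field or, via
#'   `generator = gen_params(...)`, of the generator block.
#' @return A named list (class `ccpulse_config`).
#' @export
default_config <- function(...) {
  cfg <- list(
    ecg_band = c(0.2, 45),
    acc_band = c(0.5, 7.5),
    filter_order = 4,
    zero_phase = TRUE,
    envelope_window_s = 0.1,
    pause_threshold_ms2 = 10,
    min_pause_s = 3,
    segment_duration_s = 3,
    guard_s = 0,
    detection_threshold = 0.22,
    normalization = "energy_sqrt",
    n_pr = 10,
    n_pea = 20,
    prop_training = 0.5,
    generator = gen_params(),
    seed = 1
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad) > 0L) {
    abort(sprintf("Unknown config field(s): %s", paste(bad, collapse = ", ")),
          class = "ccpulse_config_error")
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = c("ccpulse_config", "list"))
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Fields present in the file override the defaults of [default_config()];
#' the merged configuration is validated eagerly.
#'
#' @param path Path to a YAML (or JSON, which YAML subsumes) file.
#' @return A validated `ccpulse_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path), class = "ccpulse_io_error")
  }
  raw <- yaml::read_yaml(path)
  gen_overrides <- raw$generator
  raw$generator <- NULL
  cfg <- do.call(default_config, raw)
  if (!is.null(gen_overrides)) {
    cfg$generator <- do.call(gen_params, gen_overrides)
  }
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks every field against the preconditions of the stage that consumes
#' it and reports all violations at once.
#'
#' @param cfg A configuration list from [default_config()] / [read_config()].
#' @return `cfg`, invisibly, when valid; otherwise an error of class
#'   `ccpulse_config_error` listing every violation.
#' @export
validate_config <- function(cfg) {
  problems <- character(0)
  fs <- cfg$generator$sample_rate_hz
  nyq <- fs / 2
  chk_band <- function(band, name) {
    if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1]) {
      problems <<- c(problems, sprintf(
        "%s must be (low, high) with 0 < low < high.", name))
    } else if (band[2] >= nyq) {
      problems <<- c(problems, sprintf(
        "%s high cutoff %.6g Hz is at or above Nyquist (%.6g Hz at %.6g Hz sampling).",
        name, band[2], nyq, fs))
    }
  }
  chk_band(cfg$ecg_band, "ecg_band")
  chk_band(cfg$acc_band, "acc_band")
  chk_pos <- function(val, name) {
    if (!is.numeric(val) || length(val) != 1 || !is.finite(val) || val <= 0) {
      problems <<- c(problems, sprintf("%s must be a single positive number.", name))
    }
  }
  chk_pos(cfg$filter_order, "filter_order")
  chk_pos(cfg$envelope_window_s, "envelope_window_s")
  chk_pos(cfg$pause_threshold_ms2, "pause_threshold_ms2")
  chk_pos(cfg$min_pause_s, "min_pause_s")
  chk_pos(cfg$segment_duration_s, "segment_duration_s")
  chk_pos(fs, "generator$sample_rate_hz")
  if (!cfg$normalization %in% c("energy_sqrt", "energy_product")) {
    problems <- c(problems,
                  "normalization must be 'energy_sqrt' or 'energy_product'.")
  }
  if (cfg$n_pr + cfg$n_pea < 2) {
    problems <- c(problems, "n_pr + n_pea must be at least 2.")
  }
  if (cfg$prop_training <= 0 || cfg$prop_training >= 1) {
    problems <- c(problems, "prop_training must be in (0, 1).")
  }
  if (length(problems) > 0L) {
    abort(paste0("Invalid configuration:\n",
                 paste0("  - ", problems, collapse = "\n")),
          class = "ccpulse_config_error")
  }
  invisible(cfg)
}

#' Run the full synthetic study pipeline
#'
#' One-command chain: simulate a labelled segment dataset, annotate it
#' (rhythm, ABP features, heart rate), score every segment with the
#' cross-correlation detector, split by animal into training and testing,
#' optimize thresholds on the training split and evaluate MAP, CCp and HR on
#' the testing split. When `out_dir` is given, the feature table,
#' annotations, detections, a JSON report and a run manifest are written
#' there.
#'
#' @param cfg Configuration from [default_config()] / [read_config()].
#' @param out_dir Optional output directory (created if missing).
#' @param quiet Suppress per-stage progress messages.
#' @return A list: `dataset`, `annotations`, `detections`, `features`
#'   (tibbles) and `study` (the [evaluate_study()] result).
#' @export
run_pipeline <- function(cfg = default_config(), out_dir = NULL,
                         quiet = FALSE) {
  validate_config(cfg)
  say <- function(...) if (!quiet) rlang::inform(sprintf(...))

  cfg$generator$duration_s <- cfg$segment_duration_s
  ds <- generate_dataset(cfg$n_pr, cfg$n_pea, params = cfg$generator,
                         seed = cfg$seed)
  say("simulate: %d PR / %d PEA segments at %g Hz", cfg$n_pr, cfg$n_pea,
      cfg$generator$sample_rate_hz)

  ann <- annotate_segments(ds)
  say("annotate: %d organized, %d disorganized; %d PR / %d PEA by ABP",
      sum(ann$rhythm == "organized"), sum(ann$rhythm == "disorganized"),
      sum(ann$hemodynamic == "PR"), sum(ann$hemodynamic == "PEA"))

  det <- detect_pulses(ds, threshold = cfg$detection_threshold,
                       normalization = cfg$normalization)
  say("detect: %d of %d segments flagged pulse-present at CCp > %.3g",
      sum(det$decision == "pulse_present"), nrow(det),
      cfg$detection_threshold)

  ds <- split_dataset(ds, prop_training = cfg$prop_training, seed = cfg$seed)
  features <- study_feature_table(ds, annotations = ann)
  say("split: %d training / %d testing segments (animal-grouped)",
      sum(features$set == "training"), sum(features$set == "testing"))

  study <- evaluate_study(features)
  say("evaluate: testing AUC CCp %.3f, MAP %.3f, HR %.3f",
      study$performance$auc[study$performance$feature == "CCp"],
      study$performance$auc[study$performance$feature == "MAP"],
      study$performance$auc[study$performance$feature == "HR"])

  result <- list(dataset = ds, annotations = ann, detections = det,
                 features = features, study = study)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(features, file.path(out_dir, "features.csv"))
    readr::write_csv(dplyr::select(ann, -"qrs"),
                     file.path(out_dir, "annotations.csv"))
    readr::write_csv(det, file.path(out_dir, "detections.csv"))
    report <- list(
      group_stats = study$group_stats,
      ccp_map_correlation = study$ccp_map_correlation,
      thresholds = study$thresholds,
      performance = study$performance,
      auc_comparisons = study$auc_comparisons,
      rate_comparisons = study$rate_comparisons)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    manifest <- list(
      config_hash = rlang::hash(unclass(cfg)),
      seed = cfg$seed,
      n_segments = nrow(ds),
      n_training = sum(features$set == "training"),
      n_testing = sum(features$set == "testing"),
      package_version = as.character(utils::packageVersion("ccpulse")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    say("wrote report to %s", out_dir)
  }
  invisible(result)
}
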