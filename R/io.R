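#' Read a multichannel resuscitation recording from CSV
#'
#' The canonical interchange format is one CSV per recording with header
#' `time_s,ecg_mv,abp_mmhg,acc_ms2`: time in seconds, ECG in mV, arterial
#' blood pressure in mmHg and chest acceleration in m/s^2, one row per sample.
#' Lines starting with `#` before the header are treated as comments. The
#' sampling rate is inferred from the median time step and the time base must
#' be uniform to a relative tolerance of 1e-6.
#'
#' @param path Path to a waveform CSV.
#' @param record_id Label for the recording; defaults to the file name.
#' @return A tibble with columns `time_s`, `ecg_mv`, `abp_mmhg`, `acc_ms2`
#'   and attributes `sample_rate_hz` and `record_id`.
#' @seealso [write_recording()], [recording_sample_rate()]
#' @export
read_recording <- function(path, record_id = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("Recording file not found: %s", path), class = "ccpulse_io_error")
  }
  dat <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (nrow(dat) == 0L) {
    abort(sprintf("Recording file is empty: %s", path),
          class = "ccpulse_empty_input_error")
  }
  required <- c("time_s", "ecg_mv", "abp_mmhg", "acc_ms2")
  missing_cols <- setdiff(required, names(dat))
  if (length(missing_cols) > 0L) {
    abort(sprintf("Recording CSV is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "ccpulse_format_error")
  }
  dat <- dplyr::select(dat, dplyr::all_of(required))
  for (col in required) check_numeric_series(dat[[col]], col)

  fs <- NA_real_
  if (nrow(dat) >= 2L) {
    steps <- diff(dat$time_s)
    if (any(steps <= 0)) {
      abort("Time column must be strictly increasing.",
            class = "ccpulse_timing_error")
    }
    step <- median(steps)
    if (any(abs(steps - step) > 1e-6 * step)) {
      abort(sprintf(
        "Non-uniform time base: steps deviate from the median (%.9g s) by more than rel. 1e-6.",
        step), class = "ccpulse_timing_error")
    }
    fs <- 1 / step
  }

  structure(as_tibble(dat),
            sample_rate_hz = fs,
            record_id = record_id %||% sub("\\.[^.]*$", "", basename(path)),
            class = c("cpr_recording", class(as_tibble(dat))))
}

#' Write a multichannel recording to CSV
#'
#' Writes the four-channel waveform CSV read back by [read_recording()], with
#' full double precision so that write/read round-trips are lossless to well
#' below 1e-9.
#'
#' @param rec Data frame with columns `time_s`, `ecg_mv`, `abp_mmhg`,
#'   `acc_ms2` (e.g. from [read_recording()] or [gen_recording()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  required <- c("time_s", "ecg_mv", "abp_mmhg", "acc_ms2")
  missing_cols <- setdiff(required, names(rec))
  if (length(missing_cols) > 0L) {
    abort(sprintf("Recording is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "ccpulse_format_error")
  }
  out <- as.data.frame(rec)[, required]
  # format with 17 significant digits; readr::write_csv already round-trips
  # doubles, but be explicit so any reader recovers full precision
  con <- tryCatch(file(path, "w"), error = function(e) {
    abort(sprintf("Cannot open '%s' for writing: %s", path, conditionMessage(e)),
          class = "ccpulse_io_error")
  })
  on.exit(close(con))
  writeLines(paste(required, collapse = ","), con)
  lines <- do.call(paste, c(lapply(out, formatC, digits = 17, format = "g"),
                            list(sep = ",")))
  writeLines(lines, con)
  invisible(path)
}

#' Sampling rate of a recording
#'
#' @param rec A recording tibble from [read_recording()] or [gen_recording()].
#' @return Sampling rate in Hz.
#' @export
recording_sample_rate <- function(rec) {
  fs <- attr(rec, "sample_rate_hz")
  if (is.null(fs) || !is.finite(fs)) {
    if (!is.null(rec$time_s) && length(rec$time_s) >= 2L) {
      fs <- 1 / median(diff(rec$time_s))
    } else {
      abort("Recording has no usable sample-rate attribute or time column.",
            class = "ccpulse_format_error")
    }
  }
  fs
}

#' Read a per-segment feature table
#'
#' Reads the tabular per-segment features used for threshold training and
#' evaluation: a split assignment (training/testing), the reference label
#' (PR = perfusing rhythm, PEA = pulseless electrical activity), mean arterial
#' pressure, the cross-correlation peak CCp and heart rate. Column names are
#' configurable through `col_map` because external exports rarely share one
#' header convention. Only plain-text CSV is supported; spreadsheets must be
#' exported to CSV first.
#'
#' @param path Path to a CSV file.
#' @param col_map Named character vector mapping the canonical names
#'   `segment_id`, `set`, `label`, `map_mmhg`, `ccp`, `hr_bpm` to the column
#'   names used in the file. Defaults to the identity mapping.
#' @param label_map Named character vector normalizing label spellings to
#'   `"PR"`/`"PEA"` (case-insensitive match on names). Values not covered
#'   raise an annotation error.
#' @param set_map Same for the split column, normalizing to
#'   `"training"`/`"testing"`.
#' @param quiet Suppress the per-(set,label) row-count message.
#' @return A tibble with columns `segment_id`, `set`, `label`, `map_mmhg`,
#'   `ccp`, `hr_bpm`.
#' @export
read_feature_table <- function(path, col_map = NULL, label_map = NULL,
                               set_map = NULL, quiet = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("Feature table not found: %s", path), class = "ccpulse_io_error")
  }
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    abort(paste0("XLSX input is not supported; export the sheet to CSV ",
                 "and pass a `col_map` if the headers differ."),
          class = "ccpulse_format_error")
  }
  canonical <- c("segment_id", "set", "label", "map_mmhg", "ccp", "hr_bpm")
  cm <- stats::setNames(canonical, canonical)
  if (!is.null(col_map)) cm[names(col_map)] <- unname(col_map)

  dat <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  missing_cols <- setdiff(unname(cm), names(dat))
  if (length(missing_cols) > 0L) {
    abort(sprintf("Feature table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "ccpulse_format_error")
  }
  out <- tibble(
    segment_id = as.character(dat[[cm[["segment_id"]]]]),
    set        = as.character(dat[[cm[["set"]]]]),
    label      = as.character(dat[[cm[["label"]]]]),
    map_mmhg   = as.numeric(dat[[cm[["map_mmhg"]]]]),
    ccp        = as.numeric(dat[[cm[["ccp"]]]]),
    hr_bpm     = as.numeric(dat[[cm[["hr_bpm"]]]])
  )
  if (anyDuplicated(out$segment_id)) {
    abort("Feature table has duplicated segment_id values.",
          class = "ccpulse_annotation_error")
  }

  normalize <- function(x, target, extra, what) {
    map <- stats::setNames(target, tolower(target))
    if (!is.null(extra)) map[tolower(names(extra))] <- unname(extra)
    hit <- map[tolower(x)]
    if (anyNA(hit)) {
      bad <- sort(unique(x[is.na(hit)]))
      abort(sprintf("Unmapped %s value(s): %s", what,
                    paste(bad, collapse = ", ")),
            class = "ccpulse_annotation_error")
    }
    unname(hit)
  }
  out$label <- normalize(out$label, c("PR", "PEA"), label_map, "label")
  out$set <- normalize(out$set, c("training", "testing"), set_map,
                       "set assignment")
  if (!quiet) {
    counts <- dplyr::count(out, .data$set, .data$label)
    msg <- paste(sprintf("%s %s: %d", counts$set, counts$label, counts$n),
                 collapse = "; ")
    rlang::inform(paste0("Feature table rows - ", msg))
  }
  out
}
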