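#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_step geom_vline
#'   geom_hline labs facet_wrap theme_minimal annotate autoplot vars
NULL

#' @export
ggplot2::autoplot

#' Plot a cross-correlation sequence
#'
#' Normalized cross-correlation versus lag (in seconds when a sampling rate
#' is supplied), with the peak (CCp) marked.
#'
#' @param object A `cpr_xcorr` tibble from [normalized_xcorr()].
#' @param sample_rate_hz Optional sampling rate to express lags in seconds.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cpr_xcorr <- function(object, sample_rate_hz = NULL, ...) {
  pk <- peak_correlation(object)
  if (!is.null(sample_rate_hz)) {
    dat <- tibble(lag = object$lag / sample_rate_hz, value = object$value)
    pk_lag <- pk$peak_lag / sample_rate_hz
    xlab <- "lag (s)"
  } else {
    dat <- tibble(lag = object$lag, value = object$value)
    pk_lag <- pk$peak_lag
    xlab <- "lag (samples)"
  }
  ggplot(dat, aes(x = .data$lag, y = .data$value)) +
    geom_line(colour = "steelblue") +
    annotate("point", x = pk_lag, y = pk$ccp, colour = "firebrick", size = 2) +
    annotate("text", x = pk_lag, y = pk$ccp, vjust = -0.8,
             label = sprintf("CCp = %.3f", pk$ccp)) +
    labs(x = xlab, y = "normalized cross-correlation") +
    theme_minimal()
}

#' Plot the channels of a recording or segment window
#'
#' Stacked ECG / ABP / acceleration traces on a shared time axis.
#'
#' @param rec A recording tibble (`time_s`, `ecg_mv`, `abp_mmhg`,
#'   `acc_ms2`), or one row of a nested segment table.
#' @param sample_rate_hz Sampling rate, needed only for nested segment rows.
#' @return A ggplot object.
#' @export
plot_channels <- function(rec, sample_rate_hz = NULL) {
  if ("ecg" %in% names(rec) && is.list(rec[["ecg"]])) {
    fs <- sample_rate_hz %||% attr(rec, "sample_rate_hz")
    check_sample_rate(fs)
    n <- length(rec$ecg[[1]])
    rec <- tibble(time_s = seq_len(n) / fs,
                  ecg_mv = rec$ecg[[1]],
                  abp_mmhg = rec$abp[[1]],
                  acc_ms2 = rec$acc[[1]])
  }
  long <- tidyr::pivot_longer(
    dplyr::select(rec, "time_s", "ecg_mv", "abp_mmhg", "acc_ms2"),
    -"time_s", names_to = "channel", values_to = "value")
  long$channel <- factor(long$channel,
                         levels = c("ecg_mv", "abp_mmhg", "acc_ms2"),
                         labels = c("ECG (mV)", "ABP (mmHg)",
                                    "ACC (m/s²)"))
  ggplot(long, aes(x = .data$time_s, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(vars(.data$channel), ncol = 1, scales = "free_y") +
    labs(x = "time (s)", y = NULL) +
    theme_minimal()
}

#' Plot an empirical ROC curve
#'
#' @param scores Numeric scores, larger values indicating PR.
#' @param labels `"PR"`/`"PEA"` labels.
#' @param threshold Optional decision threshold to mark on the curve.
#' @return A ggplot object annotated with the AUC.
#' @export
plot_roc <- function(scores, labels, threshold = NULL) {
  labels <- as.character(labels)
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  pts <- purrr::map_dfr(cuts, function(ct) {
    cm <- confusion_metrics(scores > ct, labels)
    tibble(fpr = 1 - cm$specificity, tpr = cm$sensitivity, cut = ct)
  })
  p <- ggplot(pts, aes(x = .data$fpr, y = .data$tpr)) +
    geom_step(colour = "steelblue") +
    geom_point(size = 0.6, colour = "steelblue") +
    annotate("text", x = 0.75, y = 0.1,
             label = sprintf("AUC = %.3f", roc_auc(scores, labels))) +
    labs(x = "1 - specificity", y = "sensitivity") +
    theme_minimal()
  if (!is.null(threshold)) {
    cm <- confusion_metrics(scores > threshold, labels)
    p <- p + annotate("point", x = 1 - cm$specificity, y = cm$sensitivity,
                      colour = "firebrick", size = 2)
  }
  p
}
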