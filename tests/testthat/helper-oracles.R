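# Independent oracles used across the suite. These deliberately re-derive
# quantities from first principles (direct sums, closed forms) rather than
# calling the implementation under test.

# direct evaluation of the normalized cross-correlation sum over all lags
direct_xcorr <- function(x, y, normalization = "energy_sqrt") {
  n <- length(x)
  lags <- seq(-(n - 1L), n - 1L)
  vals <- vapply(lags, function(l) {
    nn <- seq(max(1L, 1L + l), min(n, n + l))
    sum(x[nn] * y[nn - l])
  }, numeric(1))
  denom <- if (normalization == "energy_sqrt") {
    sqrt(sum(x^2) * sum(y^2))
  } else {
    sum(x^2) * sum(y^2)
  }
  tibble::tibble(lag = lags, value = vals / denom)
}

# closed-form squared-magnitude response of the bilinear-transformed
# Butterworth band-pass (prewarped analog prototype)
analytic_bp_gain2 <- function(f, fs, lo, hi, order) {
  warp <- function(g) 2 * fs * tan(pi * g / fs)
  w <- (warp(f)^2 - warp(lo) * warp(hi)) / (warp(f) * (warp(hi) - warp(lo)))
  1 / (1 + w^(2 * order))
}

# steady-state amplitude of a sinusoid at known frequency by least squares
# over an interior stretch of the signal
sine_amplitude <- function(y, f, fs, skip_s = 3) {
  n <- length(y)
  idx <- seq(round(skip_s * fs), n - round(skip_s * fs))
  t <- idx / fs
  basis <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
  sqrt(sum(qr.solve(basis, y[idx])^2))
}

# textbook formulas for the classical tests
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(statistic = tt, df = na + nb - 2,
       p_value = 2 * pt(-abs(tt), na + nb - 2))
}

pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum(scale(x) * scale(y)) / (n - 1)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p_value = 2 * pt(-abs(tt), n - 2))
}

chisq_oracle <- function(k1, n1, k2, n2) {
  obs <- rbind(c(k1, n1 - k1), c(k2, n2 - k2))
  exp <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  x2 <- sum((obs - exp)^2 / exp)
  list(statistic = x2, p_value = pchisq(x2, 1, lower.tail = FALSE))
}

# trapezoidal area under the empirical ROC curve
trapezoid_auc <- function(scores, labels) {
  pos <- labels == "PR"
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(cuts, function(ct) mean(scores[pos] > ct), numeric(1))
  fpr <- vapply(cuts, function(ct) mean(scores[!pos] > ct), numeric(1))
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# a minimal valid recording tibble for io tests
make_recording <- function(n = 900, fs = 300) {
  tibble::tibble(
    time_s = seq_len(n) / fs,
    ecg_mv = rnorm(n),
    abp_mmhg = 80 + 20 * sin(2 * pi * 2 * seq_len(n) / fs),
    acc_ms2 = rnorm(n)
  )
}
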