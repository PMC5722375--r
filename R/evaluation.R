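#' Area under the ROC curve
#'
#' AUC computed as the probability that a randomly chosen positive (PR) score
#' exceeds a randomly chosen negative (PEA) score, with ties counted one
#' half -- the rank-sum (Mann--Whitney) form, which equals the trapezoidal
#' area under the empirical ROC curve exactly.
#'
#' @param scores Numeric scores, larger values indicating PR.
#' @param labels Labels with positive class `"PR"`, negative `"PEA"`.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  check_numeric_series(scores, "scores")
  labels <- as.character(labels)
  if (length(labels) != length(scores)) {
    abort("`scores` and `labels` must have equal length.",
          class = "ccpulse_shape_error")
  }
  pos <- labels == "PR"
  m <- sum(pos)
  n <- sum(!pos)
  if (m == 0L || n == 0L) {
    abort("AUC needs both classes present.",
          class = "ccpulse_degenerate_input_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - m * (m + 1) / 2) / (m * n)
}

#' Confusion counts and derived rates
#'
#' Sensitivity is the proportion of PR windows detected as pulse-present;
#' specificity the proportion of PEA windows detected as pulse-absent;
#' accuracy the overall proportion of correct decisions.
#'
#' @param decisions `"pulse_present"`/`"pulse_absent"` (or logical, `TRUE` =
#'   pulse present).
#' @param labels `"PR"`/`"PEA"` reference labels, same length.
#' @return One-row tibble with `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `accuracy`.
#' @export
confusion_metrics <- function(decisions, labels) {
  if (is.logical(decisions)) {
    decisions <- ifelse(decisions, "pulse_present", "pulse_absent")
  }
  decisions <- as.character(decisions)
  labels <- as.character(labels)
  if (length(decisions) != length(labels)) {
    abort("`decisions` and `labels` must have equal length.",
          class = "ccpulse_shape_error")
  }
  pos <- labels == "PR"
  det <- decisions == "pulse_present"
  tp <- sum(det & pos); fn <- sum(!det & pos)
  tn <- sum(!det & !pos); fp <- sum(det & !pos)
  tibble(tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = tp / (tp + fn),
         specificity = tn / (tn + fp),
         accuracy = (tp + tn) / length(labels))
}

new_comparison <- function(name, statistic, p_value, df = NA_real_,
                           note = NA_character_) {
  tibble(statistic_name = name, statistic = statistic,
         p_value = p_value, df = df, note = note)
}

#' Two-sample Student's t test
#'
#' Pooled-variance two-tailed t test by default (`var_equal = FALSE` gives
#' Welch). Zero pooled variance with equal means yields `t = 0, p = 1`; with
#' unequal means an infinite statistic is flagged.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param var_equal Pool the variances (default `TRUE`).
#' @return One-row tibble with `statistic_name = "t_test"`, `statistic`,
#'   `p_value`, `df`, `note`.
#' @export
students_t <- function(a, b, var_equal = TRUE) {
  check_numeric_series(a, "a", min_len = 2L)
  check_numeric_series(b, "b", min_len = 2L)
  if (sd(a) == 0 && sd(b) == 0) {
    df <- length(a) + length(b) - 2
    if (mean(a) == mean(b)) {
      return(new_comparison("t_test", 0, 1, df))
    }
    return(new_comparison("t_test", sign(mean(a) - mean(b)) * Inf, 0, df,
                          note = "infinite_statistic"))
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  new_comparison("t_test", unname(ht$statistic), ht$p.value,
                 unname(ht$parameter))
}

#' Pearson correlation with two-tailed test
#'
#' @param x,y Numeric vectors of equal length `n >= 3` with nonzero
#'   variance. The reported `statistic` is the sample correlation `r`; the
#'   p-value comes from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#'   degrees of freedom.
#' @return One-row tibble with `statistic_name = "pearson_r"`, `statistic`
#'   (= r), `p_value`, `df`.
#' @export
pearson_r <- function(x, y) {
  check_numeric_series(x, "x", min_len = 3L)
  check_numeric_series(y, "y", min_len = 3L)
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length.", class = "ccpulse_shape_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation undefined: zero variance input.",
          class = "ccpulse_degenerate_input_error")
  }
  r <- stats::cor(x, y)
  n <- length(x)
  if (abs(r) >= 1) {
    return(new_comparison("pearson_r", r, 0, n - 2))
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  new_comparison("pearson_r", unname(ht$estimate), ht$p.value,
                 unname(ht$parameter))
}

delong_placements <- function(scores, pos) {
  x <- scores[pos]
  y <- scores[!pos]
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' Compare two paired AUCs
#'
#' Z test for the difference of two AUCs computed from paired scores (two
#' features measured on the same windows). The default variance estimate is
#' DeLong's, built from the per-observation placement values of both
#' features, which accounts for their correlation; `method = "hanley"` uses
#' the Hanley--McNeil variance for each AUC and ignores the pairing.
#'
#' @param scores_a,scores_b Numeric scores of the two features on the same
#'   windows.
#' @param labels `"PR"`/`"PEA"` labels, same length.
#' @param method `"delong"` (default) or `"hanley"`.
#' @return One-row tibble with `statistic_name = "auc_z"`, `statistic` (Z),
#'   `p_value` and, in `note`, a flag when the variance is degenerate.
#' @export
compare_auc <- function(scores_a, scores_b, labels,
                        method = c("delong", "hanley")) {
  method <- match.arg(method)
  check_numeric_series(scores_a, "scores_a")
  check_numeric_series(scores_b, "scores_b")
  labels <- as.character(labels)
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels)) {
    abort("Scores and labels must have equal length.",
          class = "ccpulse_shape_error")
  }
  pos <- labels == "PR"
  m <- sum(pos)
  n <- sum(!pos)
  if (m < 2L || n < 2L) {
    abort("AUC comparison needs at least two observations per class.",
          class = "ccpulse_degenerate_input_error")
  }
  pa <- delong_placements(scores_a, pos)
  pb <- delong_placements(scores_b, pos)
  diff <- pa$auc - pb$auc
  if (method == "delong") {
    s10 <- stats::cov(cbind(pa$v10, pb$v10))
    s01 <- stats::cov(cbind(pa$v01, pb$v01))
    v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
         (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  } else {
    hm_var <- function(auc) {
      q1 <- auc / (2 - auc)
      q2 <- 2 * auc^2 / (1 + auc)
      (auc * (1 - auc) + (m - 1) * (q1 - auc^2) + (n - 1) * (q2 - auc^2)) /
        (m * n)
    }
    v <- hm_var(pa$auc) + hm_var(pb$auc)
  }
  if (v <= 0) {
    if (diff == 0) {
      return(new_comparison("auc_z", 0, 1))
    }
    return(new_comparison("auc_z", NA_real_, NA_real_,
                          note = "degenerate_variance"))
  }
  z <- diff / sqrt(v)
  new_comparison("auc_z", z, 2 * pnorm(-abs(z)))
}

#' Chi-square comparison of two proportions
#'
#' Pearson chi-square on the 2x2 table of successes and failures, one degree
#' of freedom, without continuity correction by default. A warning flag is
#' recorded in `note` when any expected cell count falls below 1.
#'
#' @param k1,n1 Successes and trials in the first group.
#' @param k2,n2 Successes and trials in the second group.
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return One-row tibble with `statistic_name = "chi_square"`, `statistic`,
#'   `p_value`, `df = 1`, `note`.
#' @export
chi_square_prop <- function(k1, n1, k2, n2, correct = FALSE) {
  if (n1 < 1 || n2 < 1 || k1 < 0 || k2 < 0 || k1 > n1 || k2 > n2) {
    abort("Need 0 <= k <= n and n >= 1 in both groups.",
          class = "ccpulse_config_error")
  }
  tab <- rbind(c(k1, n1 - k1), c(k2, n2 - k2))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  note <- if (any(expected < 1)) "expected_cell_below_1" else NA_character_
  if (k1 / n1 == k2 / n2) {
    return(new_comparison("chi_square", 0, 1, 1, note))
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  new_comparison("chi_square", unname(ht$statistic), ht$p.value, 1, note)
}

feature_column <- function(feature) {
  switch(toupper(feature),
         "CCP" = "ccp", "MAP" = "map_mmhg", "HR" = "hr_bpm",
         abort(sprintf("Unknown feature '%s' (use CCp, MAP or HR).", feature),
               class = "ccpulse_config_error"))
}

#' Evaluate a thresholded feature on one split
#'
#' Computes the AUC of the feature's scores and the confusion-based rates of
#' the thresholded decisions (`score > threshold` = pulse present) on the
#' chosen split of a feature table. Rows with missing feature values are
#' dropped with a message.
#'
#' @param features Feature table ([read_feature_table()] or
#'   [study_feature_table()]): columns `set`, `label` and the feature
#'   columns `map_mmhg`, `ccp`, `hr_bpm`.
#' @param feature `"CCp"`, `"MAP"` or `"HR"`.
#' @param model A `threshold_model` from [optimize_threshold()] (fitted on
#'   the other split), or a bare numeric threshold.
#' @param split `"testing"` (default) or `"training"`.
#' @return One-row tibble: `feature`, `split`, `threshold`, `auc`,
#'   `sensitivity`, `specificity`, `accuracy`, `tp`, `fp`, `tn`, `fn`,
#'   `n_pr`, `n_pea`.
#' @export
evaluate_feature <- function(features, feature, model,
                             split = c("testing", "training")) {
  split <- match.arg(split)
  col <- feature_column(feature)
  thr <- if (inherits(model, "threshold_model")) model$threshold else model
  dat <- features[features$set == split, , drop = FALSE]
  keep <- is.finite(dat[[col]])
  if (any(!keep)) {
    rlang::inform(sprintf("Dropping %d row(s) with missing %s.",
                          sum(!keep), feature))
    dat <- dat[keep, , drop = FALSE]
  }
  scores <- dat[[col]]
  auc <- roc_auc(scores, dat$label)
  cm <- confusion_metrics(scores > thr, dat$label)
  dplyr::bind_cols(
    tibble(feature = feature, split = split, threshold = thr, auc = auc),
    cm,
    tibble(n_pr = sum(dat$label == "PR"), n_pea = sum(dat$label == "PEA")))
}

#' Full study-style evaluation of a feature table
#'
#' Reproduces the complete analysis chain on a per-segment feature table:
#' group statistics (mean and SD of MAP, CCp and HR per class, with pooled t
#' tests), the Pearson correlation between CCp and MAP over all segments,
#' per-feature threshold optimization on the training split, test-split
#' performance, and pairwise comparisons between features (paired DeLong Z
#' for AUCs; chi-square for sensitivity, specificity and accuracy).
#'
#' @param features Feature table with columns `set`, `label`, `map_mmhg`,
#'   `ccp`, `hr_bpm`.
#' @return A list of tibbles: `group_stats`, `ccp_map_correlation`,
#'   `thresholds`, `performance`, `auc_comparisons`, `rate_comparisons`.
#' @export
evaluate_study <- function(features) {
  feats <- c("MAP", "CCp", "HR")

  group_stats <- purrr::map_dfr(feats, function(f) {
    col <- feature_column(f)
    ok <- is.finite(features[[col]])
    pr <- features[[col]][ok & features$label == "PR"]
    pea <- features[[col]][ok & features$label == "PEA"]
    tt <- students_t(pr, pea)
    tibble(feature = f,
           mean_pr = mean(pr), sd_pr = sd(pr), n_pr = length(pr),
           mean_pea = mean(pea), sd_pea = sd(pea), n_pea = length(pea),
           t_statistic = tt$statistic, p_value = tt$p_value)
  })

  ok <- is.finite(features$ccp) & is.finite(features$map_mmhg)
  ccp_map_correlation <- pearson_r(features$ccp[ok], features$map_mmhg[ok])

  train <- features[features$set == "training", , drop = FALSE]
  models <- purrr::map(feats, function(f) {
    col <- feature_column(f)
    ok <- is.finite(train[[col]])
    optimize_threshold(train[[col]][ok], train$label[ok], feature = f)
  })
  names(models) <- feats
  thresholds <- purrr::map_dfr(models, tidy)

  performance <- purrr::map_dfr(feats, function(f) {
    evaluate_feature(features, f, models[[f]], split = "testing")
  })

  test <- features[features$set == "testing", , drop = FALSE]
  pairs <- utils::combn(feats, 2, simplify = FALSE)
  auc_comparisons <- purrr::map_dfr(pairs, function(pr) {
    ca <- feature_column(pr[1]); cb <- feature_column(pr[2])
    ok <- is.finite(test[[ca]]) & is.finite(test[[cb]])
    cmp <- compare_auc(test[[ca]][ok], test[[cb]][ok], test$label[ok])
    dplyr::bind_cols(tibble(feature_a = pr[1], feature_b = pr[2]), cmp)
  })

  rate_comparisons <- purrr::map_dfr(pairs, function(pr) {
    pa <- performance[performance$feature == pr[1], ]
    pb <- performance[performance$feature == pr[2], ]
    purrr::map_dfr(c("sensitivity", "specificity", "accuracy"), function(rate) {
      kn <- switch(rate,
        sensitivity = list(pa$tp, pa$tp + pa$fn, pb$tp, pb$tp + pb$fn),
        specificity = list(pa$tn, pa$tn + pa$fp, pb$tn, pb$tn + pb$fp),
        accuracy = list(pa$tp + pa$tn, pa$tp + pa$tn + pa$fp + pa$fn,
                        pb$tp + pb$tn, pb$tp + pb$tn + pb$fp + pb$fn))
      cmp <- chi_square_prop(kn[[1]], kn[[2]], kn[[3]], kn[[4]])
      dplyr::bind_cols(tibble(feature_a = pr[1], feature_b = pr[2],
                              rate = rate), cmp)
    })
  })

  list(group_stats = group_stats,
       ccp_map_correlation = ccp_map_correlation,
       thresholds = thresholds,
       performance = performance,
       auc_comparisons = auc_comparisons,
       rate_comparisons = rate_comparisons)
}
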