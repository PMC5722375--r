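test_that("AUC equals pair counting and the trapezoidal ROC area", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c("PEA", "PR", "PEA", "PR")), 0.75)
  expect_equal(roc_auc(c(0.1, 0.2, 0.9, 0.95), c("PEA", "PEA", "PR", "PR")), 1)

  set.seed(43)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    scores <- sample(round(rnorm(n), 1))  # coarse values force ties
    labels <- sample(c("PR", "PEA"), n, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels), trapezoid_auc(scores, labels),
                 tolerance = 1e-12)
    # invariance under strictly increasing transforms
    expect_equal(roc_auc(exp(scores), labels), roc_auc(scores, labels))
  }

  # permuted labels are uninformative on average
  set.seed(44)
  scores <- rnorm(40)
  labs <- rep(c("PR", "PEA"), each = 20)
  null_auc <- replicate(400, roc_auc(scores, sample(labs)))
  expect_lt(abs(mean(null_auc) - 0.5), 0.02)

  expect_error(roc_auc(1:4, rep("PR", 4)),
               class = "ccpulse_degenerate_input_error")
})

test_that("confusion metrics reproduce hand-computed rates", {
  # consistent integer realization: 31 PR (29 detected), 79 PEA (77 correct)
  decisions <- c(rep("pulse_present", 29), rep("pulse_absent", 2),
                 rep("pulse_absent", 77), rep("pulse_present", 2))
  labels <- c(rep("PR", 31), rep("PEA", 79))
  cm <- confusion_metrics(decisions, labels)
  expect_equal(cm$tp, 29); expect_equal(cm$fn, 2)
  expect_equal(cm$tn, 77); expect_equal(cm$fp, 2)
  expect_equal(round(100 * cm$sensitivity, 1), 93.5)
  expect_equal(round(100 * cm$specificity, 1), 97.5)
  expect_equal(round(100 * cm$accuracy, 1), 96.4)

  all_right <- confusion_metrics(labels == "PR", labels)
  expect_equal(all_right$sensitivity, 1)
  expect_equal(all_right$specificity, 1)
  expect_equal(all_right$accuracy, 1)

  none <- confusion_metrics(rep("pulse_absent", 110), labels)
  expect_equal(none$sensitivity, 0)
  expect_equal(none$specificity, 1)
})

test_that("pooled t test matches the textbook formula", {
  got <- students_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$statistic, -3.674235, tolerance = 1e-6)
  expect_equal(got$df, 4)

  set.seed(47)
  for (i in 1:30) {
    a <- rnorm(sample(3:20, 1)); b <- rnorm(sample(3:20, 1), mean = 0.5)
    want <- pooled_t_oracle(a, b)
    got <- students_t(a, b)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-8)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-8)
    swapped <- students_t(b, a)
    expect_equal(swapped$statistic, -got$statistic)
    expect_equal(swapped$p_value, got$p_value)
  }

  same <- students_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  degen <- students_t(c(1, 1), c(2, 2))
  expect_true(is.infinite(degen$statistic))
  expect_equal(degen$note, "infinite_statistic")
})

test_that("Pearson correlation and its test match the closed form", {
  lin <- pearson_r(1:10, 2 * (1:10) + 1)
  expect_equal(lin$statistic, 1)
  neg <- pearson_r(1:10, -(1:10))
  expect_equal(neg$statistic, -1)

  set.seed(53)
  for (i in 1:30) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    want <- pearson_oracle(x, y)
    got <- pearson_r(x, y)
    expect_equal(got$statistic, want$r, tolerance = 1e-8)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-8)
  }
  expect_error(pearson_r(rep(1, 5), rnorm(5)),
               class = "ccpulse_degenerate_input_error")
})

test_that("chi-square proportion comparison matches the closed form", {
  same <- chi_square_prop(10, 20, 5, 10)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  near <- chi_square_prop(29, 31, 30, 31)
  expect_gt(near$p_value, 0.05)
  far <- chi_square_prop(15, 31, 29, 31)
  expect_lt(far$p_value, 0.001)

  set.seed(59)
  for (i in 1:30) {
    n1 <- sample(5:50, 1); n2 <- sample(5:50, 1)
    k1 <- sample(1:(n1 - 1), 1); k2 <- sample(1:(n2 - 1), 1)
    if (k1 / n1 == k2 / n2) next
    want <- chisq_oracle(k1, n1, k2, n2)
    got <- chi_square_prop(k1, n1, k2, n2)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-8)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-8)
  }

  low <- chi_square_prop(1, 2, 0, 2)
  expect_equal(low$note, "expected_cell_below_1")
})

test_that("paired AUC comparison agrees with the reference DeLong test", {
  identical_scores <- compare_auc(1:20, 1:20, rep(c("PR", "PEA"), 10))
  expect_equal(identical_scores$statistic, 0)
  expect_equal(identical_scores$p_value, 1)

  set.seed(61)
  for (i in 1:10) {
    y <- rep(c(1, 0), c(25, 35))
    a <- y + rnorm(60); b <- 0.4 * y + rnorm(60)
    labs <- ifelse(y == 1, "PR", "PEA")
    got <- compare_auc(a, b, labs)
    ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE, direction = "<"),
                          pROC::roc(y, b, quiet = TRUE, direction = "<"),
                          method = "delong")
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-8)
  }
})

test_that("DeLong comparison has power against a real AUC difference", {
  set.seed(67)
  rejections <- replicate(200, {
    y <- rep(c(1, 0), each = 200)
    a <- 2.326 * y + rnorm(400)   # population AUC ~ 0.95
    b <- 0.742 * y + rnorm(400)   # population AUC ~ 0.70
    compare_auc(a, b, ifelse(y == 1, "PR", "PEA"))$p_value < 0.05
  })
  expect_gt(mean(rejections), 0.95)
})

test_that("feature evaluation ties thresholds, AUC and rates together", {
  set.seed(71)
  n <- 120
  label <- rep(c("PR", "PEA"), c(40, 80))
  features <- tibble::tibble(
    segment_id = sprintf("s%03d", 1:n),
    set = rep(c("training", "testing"), 60),
    label = label,
    map_mmhg = ifelse(label == "PR", rnorm(n, 115, 20), rnorm(n, 15, 8)),
    ccp = ifelse(label == "PR", rnorm(n, 0.44, 0.1), rnorm(n, 0.067, 0.04)),
    hr_bpm = ifelse(label == "PR", rnorm(n, 159, 40), rnorm(n, 86, 40)))

  model <- optimize_threshold(
    features$ccp[features$set == "training"],
    features$label[features$set == "training"])
  # training accuracy can never fall below the majority class share
  expect_gte(model$training_accuracy,
             max(table(features$label[features$set == "training"])) / 60)

  perf <- evaluate_feature(features, "CCp", model, split = "testing")
  expect_gte(perf$auc, 0.99)          # well-separated Gaussians
  expect_equal(perf$tp + perf$fn, sum(features$set == "testing" &
                                        features$label == "PR"))
  expect_equal(perf$tn + perf$fp, sum(features$set == "testing" &
                                        features$label == "PEA"))
  expect_equal(perf$sensitivity, perf$tp / (perf$tp + perf$fn))

  study <- evaluate_study(features)
  expect_equal(nrow(study$performance), 3L)
  expect_equal(nrow(study$auc_comparisons), 3L)
  expect_equal(nrow(study$rate_comparisons), 9L)
  expect_true(all(study$performance$auc >= 0.5))
  expect_true(all(study$group_stats$mean_pr > study$group_stats$mean_pea))
  # CCp and MAP were generated correlated through the class only, but the
  # class effect dominates: r must be strongly positive
  expect_gt(study$ccp_map_correlation$statistic, 0.5)
})
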