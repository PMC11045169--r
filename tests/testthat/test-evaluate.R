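test_that("MCC matches the closed formula on forced and random cases", {
  expect_equal(mcc(10, 10, 0, 0), 1)
  expect_equal(mcc(0, 0, 10, 10), -1)
  expect_equal(mcc(8, 7, 2, 3), (8 * 7 - 2 * 3) / sqrt(10 * 11 * 9 * 10))
  expect_equal(mcc(0, 10, 0, 0), 0) # zero denominator convention
  expect_error(mcc(-1, 2, 3, 4), "non-negative")

  set.seed(13)
  for (i in 1:60) {
    cm <- rpois(4, 8)
    denom <- (cm[1] + cm[3]) * (cm[1] + cm[4]) * (cm[2] + cm[3]) *
      (cm[2] + cm[4])
    oracle <- if (denom == 0) 0 else
      (cm[1] * cm[2] - cm[3] * cm[4]) / sqrt(denom)
    expect_equal(mcc(cm[1], cm[2], cm[3], cm[4]), oracle)
  }
})

test_that("MCC is invariant to class swap and antisymmetric to negation", {
  set.seed(14)
  for (i in 1:20) {
    cm <- rpois(4, 6) + 1
    expect_equal(mcc(cm[1], cm[2], cm[3], cm[4]),
                 mcc(cm[2], cm[1], cm[4], cm[3]))
    # negating predictions: tp<->fn, tn<->fp
    expect_equal(mcc(cm[4], cm[3], cm[2], cm[1]),
                 -mcc(cm[1], cm[2], cm[3], cm[4]))
  }
})

test_that("ROC curves are monotone with correct endpoints and AUC", {
  scores <- c(0.9, 0.8, 0.3, 0.2)
  labels <- c("malignant", "malignant", "healthy", "healthy")
  curve <- roc_curve(scores, labels)
  expect_equal(curve$auc, 1)
  expect_equal(curve$fpr[1], 0)
  expect_equal(curve$tpr[1], 0)
  expect_equal(curve$fpr[length(curve$fpr)], 1)
  expect_equal(curve$tpr[length(curve$tpr)], 1)
  expect_true(all(diff(curve$fpr) >= 0) && all(diff(curve$tpr) >= 0))

  set.seed(15)
  s <- runif(200)
  l <- sample(c("malignant", "healthy"), 200, replace = TRUE)
  expect_equal(roc_curve(s, l)$auc + roc_curve(-s, l)$auc, 1,
               tolerance = 1e-12)

  expect_error(roc_curve(s, rep("healthy", 200)), "both classes")
})

test_that("null scores give AUC near one half at large n", {
  set.seed(16)
  n <- 10000
  s <- runif(n)
  l <- sample(rep(c("malignant", "healthy"), n / 2))
  auc <- roc_curve(s, l)$auc
  expect_gte(auc, 0.48)
  expect_lte(auc, 0.52)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(18)
  s <- round(runif(120), 2) # ties exercised
  l <- ifelse(runif(120) < plogis(4 * (s - 0.5)), "malignant", "healthy")
  if (length(unique(l)) < 2) skip("degenerate draw")
  ours <- roc_curve(s, l)$auc
  theirs <- suppressMessages(
    as.numeric(pROC::auc(pROC::roc(l, s, levels = c("healthy", "malignant"),
                                   direction = "<"))))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("the operating point minimizes expected misclassification cost", {
  scores <- c(0.9, 0.8, 0.3, 0.2)
  labels <- c("malignant", "malignant", "healthy", "healthy")
  curve <- roc_curve(scores, labels)
  op <- optimal_operating_point(curve, prevalence = 0.5)
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 1)
  expect_equal(op$cost, 0)

  set.seed(19)
  s <- runif(60)
  l <- ifelse(runif(60) < plogis(3 * (s - 0.5)), "malignant", "healthy")
  curve2 <- roc_curve(s, l)
  prev <- mean(l == "malignant")
  # brute-force oracle over all curve points
  for (costs in list(c(1, 1), c(1, 5), c(3, 1))) {
    op2 <- optimal_operating_point(curve2, costs[1], costs[2], prev)
    all_costs <- costs[1] * curve2$fpr * (1 - prev) +
      costs[2] * (1 - curve2$tpr) * prev
    expect_equal(op2$cost, min(all_costs))
    expect_true(all(op2$cost <= all_costs + 1e-12))
  }
  # overwhelming false-negative cost forces full sensitivity
  op3 <- optimal_operating_point(curve2, 1, 1e9, prev)
  expect_equal(op3$sensitivity, 1)
})

test_that("the MCC-optimal threshold equals an exhaustive scan", {
  scores <- c(0.9, 0.8, 0.3, 0.2)
  labels <- c("malignant", "malignant", "healthy", "healthy")
  opt <- mcc_optimal_threshold(scores, labels)
  expect_equal(opt$mcc, 1)

  s8 <- c(0.1, 0.35, 0.4, 0.55, 0.6, 0.7, 0.8, 0.95)
  l8 <- c("healthy", "healthy", "malignant", "healthy", "malignant",
          "healthy", "malignant", "malignant")
  opt8 <- mcc_optimal_threshold(s8, l8)
  brute <- sapply(unique(s8), function(t) {
    tp <- sum(s8 >= t & l8 == "malignant")
    tn <- sum(s8 < t & l8 == "healthy")
    fp <- sum(s8 >= t & l8 == "healthy")
    fn <- sum(s8 < t & l8 == "malignant")
    mcc(tp, tn, fp, fn)
  })
  expect_equal(opt8$mcc, max(brute))
  expect_warning(flat <- mcc_optimal_threshold(rep(0.4, 8), l8), "equal")
  expect_equal(flat$mcc, 0)

  # informative scores: chosen threshold beats predict-all-healthy
  expect_gt(opt8$sensitivity, 0)
})

test_that("iteration aggregation gives mean, sample SD and percentile CI", {
  agg <- aggregate_iterations(rep(0.7, 5))
  expect_equal(agg$mean, 0.7)
  expect_equal(agg$sd, 0)
  expect_equal(agg$ci, c(0.7, 0.7))

  agg2 <- aggregate_iterations(1:20)
  expect_equal(agg2$mean, 10.5)
  expect_equal(agg2$sd, sd(1:20))
  expect_equal(agg2$sd, 5.9160798, tolerance = 1e-6)
  expect_gte(agg2$ci[1], 1)
  expect_lte(agg2$ci[2], 20)
  expect_error(aggregate_iterations(1), ">= 2")
})

test_that("misclassification scatter pairs distances with outcomes", {
  truth <- data.frame(
    location_id = c("L1", "L2", "L3", "L4"),
    tumor_pct = c(80, 40, 10, 0),
    margin_distance_mean = c(0.2, 1.0, 1.8, NA))
  scores <- data.frame(
    location_id = c("L1", "L2", "L3", "L4"),
    context = "in_vivo",
    label = c("malignant", "malignant", "malignant", "healthy"),
    score = c(0.9, 0.8, 0.7, 0.1))
  ms <- misclassification_scatter(scores, truth, threshold = 0.5)
  expect_equal(nrow(ms$records), 3)
  expect_true(all(ms$records$correct))
  expect_lt(ms$pearson_r, 0)

  one <- misclassification_scatter(scores[1, ], truth, threshold = 0.5)
  expect_true(is.na(one$pearson_r))
})
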