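separable_toy <- function(n = 40) {
  set.seed(12)
  y <- rep(c("healthy", "malignant"), each = n / 2)
  x <- cbind(a = ifelse(y == "malignant", 3, -3) + rnorm(n, 0, 0.3),
             b = rnorm(n))
  list(x = x, y = y)
}

blob_data <- function(n_maj, n_min, seed = 31, sep = 2.5) {
  set.seed(seed)
  y <- c(rep("healthy", n_maj), rep("malignant", n_min))
  x <- cbind(a = c(rnorm(n_maj, 0), rnorm(n_min, sep)),
             b = c(rnorm(n_maj, 0), rnorm(n_min, sep)))
  list(x = x, y = y)
}

test_that("cv plans are patient-grouped, balanced and deterministic", {
  pats <- rep(sprintf("P%02d", 1:10), each = 3)
  labs <- rep(c("malignant", "healthy"), c(18, 12))
  plan <- make_cv_plan(pats, labs, n_folds = 5, n_iterations = 3, seed = 2)
  for (f in plan$folds) {
    expect_setequal(names(f), sprintf("P%02d", 1:10))
    expect_true(all(table(f) == 2))
  }
  plan2 <- make_cv_plan(pats, labs, n_folds = 5, n_iterations = 3, seed = 2)
  expect_identical(plan, plan2)

  big_pats <- rep(sprintf("P%03d", 1:100), each = 2)
  big_labs <- rep(rep(c("malignant", "healthy"), 50), each = 2)
  big <- make_cv_plan(big_pats, big_labs, n_iterations = 20, seed = 5)
  keys <- vapply(big$folds, function(f) paste(f, collapse = ""), "")
  expect_equal(length(unique(keys)), 20)

  expect_warning(
    make_cv_plan(rep(sprintf("P%02d", 1:8), each = 2),
                 rep(c("malignant", rep("healthy", 7)), each = 2),
                 n_folds = 5, seed = 1),
    "best-effort")
  expect_error(make_cv_plan(c("a", "b"), c("malignant", "healthy"),
                            n_folds = 5), "patients")
})

test_that("every fold of every iteration keeps patients exclusive", {
  pats <- rep(sprintf("P%02d", 1:23), each = 2)
  labs <- rep(sample(rep(c("malignant", "healthy"), c(6, 17))), each = 2)
  plan <- make_cv_plan(pats, labs, n_iterations = 10, seed = 9)
  for (f in plan$folds) {
    for (k in 1:5) {
      expect_length(intersect(names(f)[f == k], names(f)[f != k]), 0)
    }
  }
})

test_that("all four model types separate a separable toy problem", {
  toy <- separable_toy()
  for (mt in c("linear_svm", "quadratic_svm", "weighted_knn", "rusboost")) {
    fit <- fit_model(mt, toy$x, toy$y, seed = 1)
    sc <- predict_score(fit, toy$x)
    expect_true(all(sc >= 0 & sc <= 1))
    acc <- mean((sc >= 0.5) == (toy$y == "malignant"))
    expect_equal(acc, 1, info = mt)
    # determinism of refits
    fit2 <- fit_model(mt, toy$x, toy$y, seed = 1)
    expect_equal(predict_score(fit2, toy$x), sc, info = mt)
  }
  expect_error(fit_model("rusboost", toy$x[, 0], toy$y), "zero features")
  expect_error(fit_model("linear_svm", toy$x, rep("healthy", 40)),
               "both classes")
})

test_that("a one-round balanced RUSBoost reduces to its single tree", {
  toy <- separable_toy()
  ens <- rusboost_fit(toy$x, toy$y, n_rounds = 1, seed = 4)
  expect_length(ens$trees, 1)
  df <- data.frame(toy$x)
  tree_prob <- predict(ens$trees[[1]], df, type = "prob")[, "malignant"]
  expect_equal(predict(ens, toy$x), unname(tree_prob))
})

test_that("uninformative features give an uninformative 0.5 score", {
  x <- matrix(1, nrow = 30, ncol = 2)
  y <- rep(c("healthy", "malignant"), each = 15)
  ens <- rusboost_fit(x, y, n_rounds = 20, seed = 2)
  expect_equal(predict(ens, x), rep(0.5, 30), tolerance = 0.1)
})

test_that("boosting drives ensemble training error down on imbalanced blobs", {
  bl <- blob_data(180, 20, seed = 8, sep = 1.8)
  ens <- rusboost_fit(bl$x, bl$y, n_rounds = 50, seed = 3)
  expect_gt(length(ens$trees), 5)
  # cumulative ensemble error over rounds: final <= first, no sustained rise
  df <- data.frame(bl$x, check.names = FALSE)
  probs <- vapply(ens$trees, function(tr) {
    predict(tr, df, type = "prob")[, "malignant"]
  }, numeric(nrow(df)))
  cum_err <- vapply(seq_along(ens$alphas), function(t) {
    sc <- probs[, 1:t, drop = FALSE] %*% ens$alphas[1:t] / sum(ens$alphas[1:t])
    mean((sc >= 0.5) != (bl$y == "malignant"))
  }, numeric(1))
  expect_lte(cum_err[length(cum_err)], cum_err[1])
  expect_lte(min(cum_err), cum_err[1])
})

test_that("undersampling and boosting lift minority recall over a plain tree", {
  bl <- blob_data(190, 10, seed = 44, sep = 1.5)
  ens <- rusboost_fit(bl$x, bl$y, n_rounds = 50, seed = 7)
  sc <- predict(ens, bl$x)
  recall_rus <- mean(sc[bl$y == "malignant"] >= 0.5)
  plain <- rpart::rpart(y ~ ., data = data.frame(bl$x, y = factor(bl$y)),
                        method = "class",
                        control = rpart::rpart.control(maxdepth = 5,
                                                       xval = 0))
  pred_plain <- predict(plain, data.frame(bl$x), type = "class")
  recall_plain <- mean(pred_plain[bl$y == "malignant"] == "malignant")
  expect_gt(recall_rus, recall_plain - 1e-9)
  expect_gte(recall_rus, 0.8)
})

test_that("trained artifacts are self-contained, deterministic and order-invariant", {
  co <- tiny_cohort(seed = 19)
  art <- train_margin_model(co$measurements, co$truth,
                            model_type = "rusboost",
                            hyper = list(n_rounds = 30), seed = 6)
  sc <- score_margin_model(art, co$measurements)
  # artifact contract: scoring the training set reproduces stored scores
  expect_equal(sc, art$training_scores)
  # order invariance
  perm <- rev(seq_along(co$measurements))
  sc_rev <- score_margin_model(art, co$measurements[perm])
  merged <- merge(sc, sc_rev, by = "location_id")
  expect_equal(merged$score.x, merged$score.y)
  # separation on simulated classes
  lab <- co$truth$label[match(sc$location_id, co$truth$location_id)]
  expect_gt(mean(sc$score[lab == "malignant"]),
            mean(sc$score[lab == "healthy"]))
})
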