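# Classifier layer: patient-grouped CV planning, the four model types
# (linear SVM, quadratic SVM, distance-weighted KNN, RUSBoost) and a common
# continuous-score interface. RUSBoost -- AdaBoost with weighted random
# undersampling of the majority class before each weak-learner fit -- is
# implemented here on rpart stumps-to-depth-5 trees; the SVMs delegate to
# e1071 with Platt-style probability calibration.

#' Build a patient-grouped repeated cross-validation plan
#'
#' Every location of one patient shares a fold, so no patient contributes
#' to both the training and the test side of any split. Partitions are
#' stratified so that each fold receives malignant-bearing patients as
#' evenly as feasible; with fewer malignant patients than folds a warning
#' is issued and stratification is best-effort.
#'
#' @param patient_ids Character vector, one entry per location.
#' @param labels `"malignant"`/`"healthy"` per location.
#' @param n_folds,n_iterations Plan shape (defaults 5 and 20).
#' @param seed Master seed; iteration partitions use derived sub-seeds.
#' @return Object of class `cv_plan`: list `folds` of length
#'   `n_iterations`, each a named integer vector patient -> fold.
#' @export
make_cv_plan <- function(patient_ids, labels, n_folds = 5L,
                         n_iterations = 20L, seed = 1L) {
  patients <- unique(patient_ids)
  if (length(patients) < n_folds) {
    abort_input("need >= %d patients for %d folds", n_folds, n_folds)
  }
  if (length(unique(labels)) < 2L) abort_input("labels contain a single class")
  pat_mal <- vapply(patients, function(p) {
    any(labels[patient_ids == p] == "malignant")
  }, logical(1))
  if (sum(pat_mal) < n_folds) {
    warning("fewer malignant patients (", sum(pat_mal), ") than folds (",
            n_folds, "); stratification is best-effort")
  }
  folds <- lapply(seq_len(n_iterations), function(it) {
    with_seed(derive_seed(seed, paste0("cv-iteration-", it)), {
      counts <- integer(n_folds)
      out <- stats::setNames(integer(length(patients)), patients)
      # malignant-bearing patients first, then the rest; each shuffled
      # patient goes to the currently smallest fold (random tie-break), so
      # folds stay size-balanced while the malignant patients spread evenly
      for (group in list(patients[pat_mal], patients[!pat_mal])) {
        if (!length(group)) next
        priority <- sample.int(n_folds)
        for (p in sample(group)) {
          f <- order(counts, priority)[1L]
          out[p] <- f
          counts[f] <- counts[f] + 1L
        }
      }
      out
    })
  })
  structure(list(folds = folds, n_folds = as.integer(n_folds),
                 n_iterations = as.integer(n_iterations), seed = seed),
            class = "cv_plan")
}

#' Fit a RUSBoost ensemble
#'
#' Per boosting round: the majority class is randomly undersampled without
#' replacement (sampling probabilities proportional to the current boosting
#' weights) until the target minority:majority ratio is met; a depth-limited
#' classification tree is fitted on the resampled set with its boosting
#' weights; the weighted error `e_t` of the tree on the full training set is
#' computed; rounds with `e_t >= 0.5` are discarded and resampled (up to
#' `max_retries` times); weights are updated AdaBoost-style with
#' `alpha_t = learning_rate * ln((1 - e_t) / e_t)`. The ensemble score is
#' the alpha-weighted mean of the trees' malignant-class probabilities,
#' in `[0, 1]`; an ensemble that accepted no rounds scores 0.5 everywhere.
#'
#' @param x Numeric feature matrix.
#' @param y Labels with positive class `"malignant"`.
#' @param n_rounds Number of boosting rounds (default 100).
#' @param learning_rate Shrinkage on alpha (default 0.1).
#' @param max_depth Tree depth limit (default 5).
#' @param class_ratio Target minority:majority ratio after undersampling
#'   (default 1, i.e. 50:50).
#' @param seed RNG seed for the undersampling draws.
#' @param max_retries Resampling attempts per round when `e_t >= 0.5`.
#' @return Object of class `rusboost`: `trees`, `alphas`, `errors` (the
#'   per-round weighted training errors of accepted rounds), `levels`.
#' @export
rusboost_fit <- function(x, y, n_rounds = 100L, learning_rate = 0.1,
                         max_depth = 5L, class_ratio = 1, seed = 1L,
                         max_retries = 10L) {
  stopifnot(n_rounds >= 1L)
  y <- factor(y)
  if (nlevels(y) != 2L || !"malignant" %in% levels(y)) {
    abort_input("y must be two-class with a 'malignant' level")
  }
  if (!any(y == "malignant") || !any(y != "malignant")) {
    abort_input("both classes must be present")
  }
  x <- as.matrix(x)
  n <- nrow(x)
  counts <- table(y)
  minority <- names(counts)[which.min(counts)]
  min_idx <- which(y == minority)
  maj_idx <- which(y != minority)
  n_take <- min(length(maj_idx),
                max(1L, as.integer(round(length(min_idx) / class_ratio))))
  df <- data.frame(.y = y, x, check.names = FALSE)
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = 0, minsplit = 5L,
                               xval = 0L)
  trees <- list()
  alphas <- numeric(0)
  errors <- numeric(0)
  w <- rep(1 / n, n)
  with_seed(derive_seed(seed, "rusboost"), {
    for (t in seq_len(n_rounds)) {
      accepted <- FALSE
      for (try in seq_len(max_retries)) {
        take <- if (n_take < length(maj_idx)) {
          sample(maj_idx, n_take, prob = w[maj_idx])
        } else {
          maj_idx
        }
        sub <- c(min_idx, take)
        fit <- rpart::rpart(.y ~ ., data = df[sub, , drop = FALSE],
                            weights = w[sub] / sum(w[sub]) * length(sub),
                            method = "class", control = ctrl)
        pred <- predict(fit, df, type = "class")
        miss <- pred != y
        eps <- sum(w[miss])
        if (eps < 0.5) {
          accepted <- TRUE
          break
        }
      }
      if (!accepted) break
      eps <- max(eps, 1e-10)
      alpha <- learning_rate * log((1 - eps) / eps)
      trees[[length(trees) + 1L]] <- fit
      alphas <- c(alphas, alpha)
      errors <- c(errors, eps)
      w <- w * exp(alpha * miss)
      w <- w / sum(w)
    }
  })
  structure(list(trees = trees, alphas = alphas, errors = errors,
                 levels = levels(y)),
            class = "rusboost")
}

#' @export
predict.rusboost <- function(object, newdata, ...) {
  newdata <- as.data.frame(as.matrix(newdata), check.names = FALSE)
  if (!length(object$trees)) return(rep(0.5, nrow(newdata)))
  probs <- vapply(object$trees, function(tr) {
    predict(tr, newdata, type = "prob")[, "malignant"]
  }, numeric(nrow(newdata)))
  probs <- matrix(probs, nrow = nrow(newdata))
  out <- as.vector(probs %*% object$alphas) / sum(object$alphas)
  pmin(pmax(out, 0), 1) # guard float roundoff of the weighted mean
}

#' Default hyperparameters of the four model types
#'
#' @return Named list of per-model hyperparameter lists.
#' @export
default_hyperparameters <- function() {
  list(
    linear_svm = list(cost = 1),
    quadratic_svm = list(cost = 1, coef0 = 1),
    weighted_knn = list(k = 10L),
    rusboost = list(n_rounds = 100L, learning_rate = 0.1, max_depth = 5L,
                    class_ratio = 1)
  )
}

#' Fit one core classifier on a prepared feature matrix
#'
#' `x` is expected to be already reduced to the selected features and
#' standardized; [train_margin_model()] wraps this with the full
#' preprocessing state.
#'
#' @param model_type One of `"linear_svm"`, `"quadratic_svm"`,
#'   `"weighted_knn"`, `"rusboost"`.
#' @param x Numeric feature matrix.
#' @param y Labels (`"malignant"` / `"healthy"`).
#' @param hyper Hyperparameter list (see [default_hyperparameters()]).
#' @param seed RNG seed (Platt calibration folds, RUS draws).
#' @return Object of class `margin_fit`.
#' @export
fit_model <- function(model_type = c("linear_svm", "quadratic_svm",
                                     "weighted_knn", "rusboost"),
                      x, y, hyper = NULL, seed = 1L) {
  model_type <- match.arg(model_type)
  hyper <- utils::modifyList(default_hyperparameters()[[model_type]],
                             hyper %||% list())
  y <- factor(y, levels = c("healthy", "malignant"))
  if (any(is.na(y)) || nlevels(droplevels(y)) < 2L) {
    abort_input("training labels must contain both classes")
  }
  x <- as.matrix(x)
  if (!ncol(x)) abort_input("refusing to train on zero features")
  fit <- switch(model_type,
    linear_svm = with_seed(derive_seed(seed, "svm"), {
      e1071::svm(x, y, kernel = "linear", cost = hyper$cost, scale = FALSE,
                 probability = TRUE)
    }),
    quadratic_svm = with_seed(derive_seed(seed, "svm"), {
      e1071::svm(x, y, kernel = "polynomial", degree = 2L,
                 coef0 = hyper$coef0, cost = hyper$cost, scale = FALSE,
                 probability = TRUE)
    }),
    weighted_knn = list(x = x, y = y, k = hyper$k),
    rusboost = rusboost_fit(x, y, n_rounds = hyper$n_rounds,
                            learning_rate = hyper$learning_rate,
                            max_depth = hyper$max_depth,
                            class_ratio = hyper$class_ratio, seed = seed)
  )
  structure(list(model_type = model_type, fit = fit, hyper = hyper),
            class = "margin_fit")
}

# Inverse-squared-distance weighted KNN malignancy score.
.knn_score <- function(fit, newx) {
  tx <- fit$x
  d2 <- outer(rowSums(newx^2), rep(1, nrow(tx))) +
    outer(rep(1, nrow(newx)), rowSums(tx^2)) - 2 * newx %*% t(tx)
  d2 <- pmax(d2, 0)
  k <- min(fit$k, nrow(tx))
  is_mal <- fit$y == "malignant"
  vapply(seq_len(nrow(newx)), function(i) {
    nn <- order(d2[i, ])[seq_len(k)]
    dd <- d2[i, nn]
    if (any(dd < 1e-24)) {
      mean(is_mal[nn[dd < 1e-24]])
    } else {
      w <- 1 / dd
      sum(w * is_mal[nn]) / sum(w)
    }
  }, numeric(1))
}

#' Continuous malignancy score of a fitted core model
#'
#' @param fit A [fit_model()] result.
#' @param x Feature matrix on the same columns and scaling as training.
#' @return Numeric scores in `[0, 1]`, higher = more malignant.
#' @export
predict_score <- function(fit, x) {
  stopifnot(inherits(fit, "margin_fit"))
  x <- as.matrix(x)
  switch(fit$model_type,
    linear_svm = ,
    quadratic_svm = {
      pr <- attr(predict(fit$fit, x, probability = TRUE), "probabilities")
      as.vector(pr[, "malignant"])
    },
    weighted_knn = .knn_score(fit$fit, x),
    rusboost = predict(fit$fit, x)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
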