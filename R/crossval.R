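# Patient-grouped repeated cross-validation driver and the self-contained
# model artifact (train once / score anywhere) API.
#
# Within each (iteration, fold): the test set is the in vivo locations of
# the test-fold patients; the training set is the regime-filtered locations
# of the remaining patients. The MSC reference, MRMR selection and feature
# scaling are all fitted on the training fold only and travel with the
# fold's models, so no test information leaks into any fitted state.

.regimes <- c("both", "ex_vivo_only", "in_vivo_only")

.regime_filter <- function(context, regime) {
  switch(regime,
    both = rep(TRUE, length(context)),
    ex_vivo_only = context == "ex_vivo",
    in_vivo_only = context == "in_vivo")
}

# Feature columns whose values scale with spectrum amplitude. MSC maps a
# spectrum x to (x - a) / b; chord slope and chord deficit scale by 1 / b
# while all wavelength-valued features are invariant, so fold-specific MSC
# can be applied to precomputed raw features by rescaling those columns.
.amplitude_ops <- function(nm) {
  op <- sub(".*\\.", "", nm)
  op %in% c("slope", "max_diff")
}

# Per-spectrum MSC slope b against a reference mean (vectorized OLS).
.msc_slopes <- function(spectra, ref_mean) {
  mc <- ref_mean - mean(ref_mean)
  as.vector(spectra %*% mc) / sum(mc^2)
}

# Feature table for a set of locations under a fold's MSC reference, built
# from precomputed raw (un-normalized) features via the 1/b rescaling.
# Falls back to explicit normalization for spectra with non-positive b.
.fold_features <- function(prep, raw_feat, loc_ids, ref_mean, ranges,
                           sg_window, sg_order) {
  nm <- colnames(raw_feat)
  scale_col <- .amplitude_ops(nm)
  n_per_fiber <- sum(scale_col) / 5L
  out <- raw_feat[loc_ids, , drop = FALSE]
  b_all <- .msc_slopes(prep$spectra, ref_mean)
  for (i in seq_along(loc_ids)) {
    rows <- prep$index$row[prep$index$location_id == loc_ids[i]]
    b <- b_all[rows]
    if (any(b <= 0)) {
      norm <- msc_normalize(prep$spectra[rows, , drop = FALSE],
                            structure(list(wavelengths = ANALYSIS_GRID,
                                           mean_intensities = ref_mean,
                                           n_contributing = 1L),
                                      class = "msc_reference"))
      out[i, ] <- extract_features(norm, ranges, sg_window, sg_order)
    } else {
      for (f in 1:5) {
        cols <- scale_col & grepl(paste0("^f", f, "\\."), nm)
        out[i, cols] <- out[i, cols] / b[f]
      }
    }
  }
  out
}

# Standardization parameters fitted on training rows.
.fit_scaler <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  list(mean = mu, sd = sd)
}

.apply_scaler <- function(x, scaler) {
  sweep(sweep(x, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}

#' Run patient-grouped repeated cross-validation
#'
#' Executes the full per-fold pipeline -- training-fold MSC reference,
#' feature extraction, MRMR selection at the importance threshold, feature
#' standardization, model fitting, and scoring of the fold's in vivo test
#' locations -- for each requested model type, sharing the fold's feature
#' work across models. Patient-level train/test exclusivity is asserted on
#' every fold.
#'
#' @param cohort List with `measurements` and `truth` (see
#'   [simulate_cohort()] or [read_cohort_csv()]).
#' @param model_types Character vector of model types to fit per fold.
#' @param regime Training regime: `"both"`, `"ex_vivo_only"` or
#'   `"in_vivo_only"`. The test set is always in vivo.
#' @param n_folds,n_iterations CV shape (defaults 5 folds, 20 iterations).
#' @param seed Master seed for partitions, RUS draws and calibration.
#' @param mrmr_threshold Importance-score cut (default 0.015 bits).
#' @param mrmr_bins,mrmr_scheme MI discretization and MRMR scheme.
#' @param mrmr_max_features Greedy ranking depth per fold (default 60; the
#'   threshold is applied within this sequence).
#' @param ranges,sg_window,sg_order Feature-extraction configuration.
#' @param stitch_policy Spectrometer-overlap policy.
#' @param hyperparameters Named list of per-model hyperparameter overrides.
#' @return Object of class `margin_cv`: `scores` (data.frame with one row
#'   per model x iteration x scored location), `selections` (per-fold
#'   selected features), `leakage_ok`, and the resolved settings.
#' @export
run_cross_validation <- function(cohort,
                                 model_types = "rusboost",
                                 regime = .regimes,
                                 n_folds = 5L, n_iterations = 20L,
                                 seed = 1L,
                                 mrmr_threshold = 0.015,
                                 mrmr_bins = 10L, mrmr_scheme = "mid",
                                 mrmr_max_features = 60L,
                                 ranges = default_feature_ranges(),
                                 sg_window = 11L, sg_order = 2L,
                                 stitch_policy = "crossfade",
                                 hyperparameters = list()) {
  regime <- match.arg(regime)
  truth <- cohort$truth
  prep <- preprocess_cohort(cohort$measurements, stitch_policy = stitch_policy)

  loc_ids <- unique(prep$index$location_id)
  loc_meta <- truth[match(loc_ids, truth$location_id), ]
  raw_feat <- matrix(NA_real_, length(loc_ids), 5L * nrow(ranges) * 5L,
                     dimnames = list(loc_ids, feature_names(ranges)))
  for (i in seq_along(loc_ids)) {
    rows <- prep$index$row[prep$index$location_id == loc_ids[i]]
    raw_feat[i, ] <- extract_features(prep$spectra[rows, , drop = FALSE],
                                      ranges, sg_window, sg_order)
  }

  plan <- make_cv_plan(loc_meta$patient_id, loc_meta$label,
                       n_folds = n_folds, n_iterations = n_iterations,
                       seed = seed)
  score_rows <- list()
  selection_rows <- list()
  leakage_ok <- TRUE
  for (it in seq_len(plan$n_iterations)) {
    fold_of <- plan$folds[[it]]
    for (fold in seq_len(plan$n_folds)) {
      test_patients <- names(fold_of)[fold_of == fold]
      train_patients <- names(fold_of)[fold_of != fold]
      if (length(intersect(test_patients, train_patients))) {
        leakage_ok <- FALSE
        stop("patient overlap between train and test folds")
      }
      is_test <- loc_meta$patient_id %in% test_patients &
        loc_meta$context == "in_vivo"
      is_train <- loc_meta$patient_id %in% train_patients &
        .regime_filter(loc_meta$context, regime)
      if (!any(is_test) || length(unique(loc_meta$label[is_train])) < 2L) next

      train_rows <- prep$index$row[prep$index$location_id %in%
                                     loc_ids[is_train]]
      ref_mean <- colMeans(prep$spectra[train_rows, , drop = FALSE])
      ft_train <- .fold_features(prep, raw_feat, loc_ids[is_train], ref_mean,
                                 ranges, sg_window, sg_order)
      ft_test <- .fold_features(prep, raw_feat, loc_ids[is_test], ref_mean,
                                ranges, sg_window, sg_order)
      y_train <- loc_meta$label[is_train]

      ranking <- mrmr_rank(ft_train, y_train, bins = mrmr_bins,
                           scheme = mrmr_scheme,
                           max_features = mrmr_max_features)
      selected <- apply_threshold(ranking, mrmr_threshold)
      if (!length(selected)) next
      selection_rows[[length(selection_rows) + 1L]] <- data.frame(
        iteration = it, fold = fold, feature = selected,
        rank = seq_along(selected),
        score = ranking$ranking$score[match(selected,
                                            ranking$ranking$feature)],
        stringsAsFactors = FALSE)

      scaler <- .fit_scaler(ft_train[, selected, drop = FALSE])
      x_train <- .apply_scaler(ft_train[, selected, drop = FALSE], scaler)
      x_test <- .apply_scaler(ft_test[, selected, drop = FALSE], scaler)
      fold_seed <- derive_seed(seed, sprintf("fit-it%d-fold%d", it, fold))
      for (mt in model_types) {
        fit <- fit_model(mt, x_train, y_train,
                         hyper = hyperparameters[[mt]], seed = fold_seed)
        score_rows[[length(score_rows) + 1L]] <- data.frame(
          model_type = mt, iteration = it, fold = fold,
          location_id = loc_ids[is_test],
          patient_id = loc_meta$patient_id[is_test],
          context = loc_meta$context[is_test],
          label = loc_meta$label[is_test],
          score = predict_score(fit, x_test),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(
    list(scores = do.call(rbind, score_rows),
         selections = do.call(rbind, selection_rows),
         leakage_ok = leakage_ok,
         regime = regime, model_types = model_types,
         n_folds = n_folds, n_iterations = n_iterations, seed = seed,
         mrmr_threshold = mrmr_threshold),
    class = "margin_cv")
}

#' Modal feature selection across folds
#'
#' Per-fold MRMR selections differ; the reported "optimum feature" list is
#' the modal selection: features chosen in at least `min_frequency` of the
#' folds, ordered by selection frequency and then by mean within-fold rank.
#'
#' @param cv A [run_cross_validation()] result.
#' @param min_frequency Minimum fraction of folds (default 0.5).
#' @return data.frame: feature, frequency, mean_rank, mean_score.
#' @export
modal_selection <- function(cv, min_frequency = 0.5) {
  stopifnot(inherits(cv, "margin_cv"))
  sel <- cv$selections
  if (is.null(sel) || !nrow(sel)) return(
    data.frame(feature = character(0), frequency = numeric(0),
               mean_rank = numeric(0), mean_score = numeric(0)))
  n_folds_run <- nrow(unique(sel[, c("iteration", "fold")]))
  agg <- do.call(rbind, lapply(split(sel, sel$feature), function(d) {
    data.frame(feature = d$feature[1], frequency = nrow(d) / n_folds_run,
               mean_rank = mean(d$rank), mean_score = mean(d$score),
               stringsAsFactors = FALSE)
  }))
  agg <- agg[agg$frequency >= min_frequency, , drop = FALSE]
  agg <- agg[order(-agg$frequency, agg$mean_rank), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Train a self-contained margin classification model
#'
#' Fits the full pipeline on the supplied (training) measurements: MSC
#' reference, feature extraction, MRMR selection, standardization and the
#' core classifier. The returned artifact carries every piece of fitted
#' state needed to score new raw measurements.
#'
#' @param measurements List of `raw_measurement` (the training set; apply
#'   any regime filter before calling).
#' @param truth Ground-truth data.frame covering the training locations.
#' @param model_type One of the four model types.
#' @param mrmr_threshold,mrmr_bins,mrmr_scheme,mrmr_max_features,ranges,sg_window,sg_order,stitch_policy
#'   Pipeline configuration (see [run_cross_validation()]).
#' @param hyper Hyperparameter overrides for the core model.
#' @param seed RNG seed.
#' @return Object of class `margin_model`.
#' @export
train_margin_model <- function(measurements, truth,
                               model_type = "rusboost",
                               mrmr_threshold = 0.015, mrmr_bins = 10L,
                               mrmr_scheme = "mid", mrmr_max_features = 60L,
                               ranges = default_feature_ranges(),
                               sg_window = 11L, sg_order = 2L,
                               stitch_policy = "crossfade",
                               hyper = NULL, seed = 1L) {
  prep <- preprocess_cohort(measurements, stitch_policy = stitch_policy)
  reference <- fit_msc_reference(prep$spectra)
  ft <- cohort_feature_table(prep, reference, truth, ranges,
                             sg_window, sg_order)
  feat_cols <- setdiff(names(ft), c("location_id", "patient_id", "context",
                                    "label"))
  ranking <- mrmr_rank(as.matrix(ft[, feat_cols]), ft$label,
                       bins = mrmr_bins, scheme = mrmr_scheme,
                       max_features = mrmr_max_features)
  selected <- apply_threshold(ranking, mrmr_threshold)
  if (!length(selected)) abort_input("refusing to train on zero features")
  scaler <- .fit_scaler(as.matrix(ft[, selected, drop = FALSE]))
  x <- .apply_scaler(as.matrix(ft[, selected, drop = FALSE]), scaler)
  fit <- fit_model(model_type, x, ft$label, hyper = hyper, seed = seed)
  artifact <- structure(
    list(model_type = model_type, fit = fit, msc_reference = reference,
         selected_features = selected, scaler = scaler, ranking = ranking,
         ranges = ranges, sg_window = sg_window, sg_order = sg_order,
         stitch_policy = stitch_policy, seed = seed),
    class = "margin_model")
  artifact$training_scores <- score_margin_model(artifact, measurements)
  artifact
}

#' Score raw measurements with a trained margin model
#'
#' Applies the artifact's stored MSC reference, feature ranges, selected
#' feature subset and scaler, then the core model. Deterministic and
#' invariant to the ordering of the input locations.
#'
#' @param artifact A [train_margin_model()] result.
#' @param measurements List of `raw_measurement` objects.
#' @return data.frame: location_id, patient_id, context, score.
#' @export
score_margin_model <- function(artifact, measurements) {
  stopifnot(inherits(artifact, "margin_model"))
  prep <- preprocess_cohort(measurements,
                            stitch_policy = artifact$stitch_policy)
  norm <- msc_normalize(prep$spectra, artifact$msc_reference)
  loc_ids <- unique(prep$index$location_id)
  fmat <- matrix(NA_real_, length(loc_ids),
                 5L * nrow(artifact$ranges) * 5L,
                 dimnames = list(loc_ids, feature_names(artifact$ranges)))
  for (i in seq_along(loc_ids)) {
    rows <- prep$index$row[prep$index$location_id == loc_ids[i]]
    fmat[i, ] <- extract_features(norm[rows, , drop = FALSE],
                                  artifact$ranges, artifact$sg_window,
                                  artifact$sg_order)
  }
  x <- .apply_scaler(fmat[, artifact$selected_features, drop = FALSE],
                     artifact$scaler)
  meta_idx <- match(loc_ids, prep$index$location_id)
  data.frame(location_id = loc_ids,
             patient_id = prep$index$patient_id[meta_idx],
             context = prep$index$context[meta_idx],
             score = predict_score(artifact$fit, x),
             stringsAsFactors = FALSE)
}
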