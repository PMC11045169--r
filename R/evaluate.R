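# Evaluation: Matthews correlation coefficient, ROC analysis, operating
# points, iteration-level aggregation and the tumor-percentage vs
# margin-distance misclassification analysis.

#' Matthews correlation coefficient
#'
#' `MCC = (tp * tn - fp * fn) / sqrt((tp + fp)(tp + fn)(tn + fp)(tn + fn))`,
#' in `[-1, 1]`. If any factor of the denominator is zero the coefficient is
#' undefined and 0 is returned by convention.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts (positive class:
#'   malignant).
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(tp, tn, fp, fn) {
  if (any(c(tp, tn, fp, fn) < 0)) abort_input("counts must be non-negative")
  tp <- as.double(tp); tn <- as.double(tn)
  fp <- as.double(fp); fn <- as.double(fn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

.confusion <- function(scores, labels, threshold) {
  pred_mal <- scores >= threshold
  is_mal <- labels == "malignant"
  c(tp = sum(pred_mal & is_mal), tn = sum(!pred_mal & !is_mal),
    fp = sum(pred_mal & !is_mal), fn = sum(!pred_mal & is_mal))
}

#' ROC curve
#'
#' Threshold sweep over the unique scores (predicted malignant when
#' `score >= threshold`), with tied scores grouped into one step; AUC by the
#' trapezoidal rule. The curve starts at (0, 0) (threshold above every
#' score) and ends at (1, 1).
#'
#' @param scores Continuous malignancy scores.
#' @param labels `"malignant"` / `"healthy"` per score.
#' @return Object of class `roc_points`: `thresholds` (descending, first is
#'   `Inf`), `fpr`, `tpr`, `auc`.
#' @export
roc_curve <- function(scores, labels) {
  is_mal <- labels == "malignant"
  n_pos <- sum(is_mal)
  n_neg <- sum(!is_mal)
  if (n_pos == 0 || n_neg == 0) abort_input("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- is_mal[ord]
  grp_end <- c(which(diff(s) != 0), length(s)) # last index of each tie group
  tp <- cumsum(y)[grp_end]
  fp <- cumsum(!y)[grp_end]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = c(Inf, s[grp_end]), fpr = fpr, tpr = tpr,
                 auc = auc),
            class = "roc_points")
}

#' Minimum-average-misclassification-cost operating point
#'
#' Minimizes `cost_fp * fpr * (1 - prevalence) + cost_fn * (1 - tpr) *
#' prevalence` over the curve points; ties break toward higher sensitivity.
#'
#' @param curve A [roc_curve()] result.
#' @param cost_fp,cost_fn Misclassification costs (defaults 1 and 1).
#' @param prevalence Malignant prevalence used to weight the costs; defaults
#'   to the empirical prevalence must be supplied by the caller.
#' @return List: `threshold`, `sensitivity`, `specificity`, `cost`.
#' @export
optimal_operating_point <- function(curve, cost_fp = 1, cost_fn = 1,
                                    prevalence = 0.5) {
  stopifnot(inherits(curve, "roc_points"))
  cost <- cost_fp * curve$fpr * (1 - prevalence) +
    cost_fn * (1 - curve$tpr) * prevalence
  best <- which(cost == min(cost))
  k <- best[which.max(curve$tpr[best])]
  list(threshold = curve$thresholds[k], sensitivity = curve$tpr[k],
       specificity = 1 - curve$fpr[k], cost = cost[k])
}

#' Threshold with the highest MCC
#'
#' Exhaustive scan over the unique scores (cut: predicted malignant when
#' `score >= threshold`); ties break toward higher sensitivity. If all
#' scores are equal every threshold gives MCC 0; the single score is
#' returned with a warning.
#'
#' @param scores,labels As in [roc_curve()].
#' @return List: `threshold`, `mcc`, `sensitivity`, `specificity`.
#' @export
mcc_optimal_threshold <- function(scores, labels) {
  if (length(unique(labels)) < 2L) abort_input("both classes must be present")
  cand <- sort(unique(scores), decreasing = TRUE)
  if (length(cand) == 1L) {
    warning("all scores equal; MCC is 0 at every threshold")
    cm <- .confusion(scores, labels, cand)
    return(list(threshold = cand, mcc = 0,
                sensitivity = cm["tp"] / (cm["tp"] + cm["fn"]),
                specificity = cm["tn"] / (cm["tn"] + cm["fp"])))
  }
  best <- list(mcc = -Inf, sensitivity = -Inf)
  for (t in cand) {
    cm <- .confusion(scores, labels, t)
    m <- mcc(cm["tp"], cm["tn"], cm["fp"], cm["fn"])
    sens <- cm[["tp"]] / (cm[["tp"]] + cm[["fn"]])
    if (m > best$mcc + 1e-12 ||
        (abs(m - best$mcc) <= 1e-12 && sens > best$sensitivity)) {
      best <- list(threshold = t, mcc = m, sensitivity = sens,
                   specificity = cm[["tn"]] / (cm[["tn"]] + cm[["fp"]]))
    }
  }
  best
}

#' Aggregate per-iteration metrics
#'
#' @param values Numeric vector of iteration-level metric values (>= 2).
#' @param conf_level Confidence level of the percentile interval.
#' @return List: `mean`, `sd` (sample SD), `ci` (percentile interval of the
#'   iteration-level values).
#' @export
aggregate_iterations <- function(values, conf_level = 0.95) {
  if (length(values) < 2L) abort_input("need >= 2 iterations")
  alpha <- (1 - conf_level) / 2
  list(mean = mean(values), sd = stats::sd(values),
       ci = unname(stats::quantile(values, c(alpha, 1 - alpha))))
}

#' Tumor-percentage vs margin-distance misclassification scatter
#'
#' For every malignant in vivo location scored at the chosen threshold:
#' its mean tumor-margin distance, tumor area percentage and whether it was
#' classified correctly, plus the Pearson correlation between tumor
#' percentage and distance over those locations (NA with fewer than 3).
#'
#' @param scores data.frame with columns `location_id`, `context`, `label`,
#'   `score` (a `margin_cv$scores` subset, possibly spanning iterations;
#'   per-location scores are averaged first).
#' @param truth Ground-truth data.frame.
#' @param threshold Classification threshold on the score.
#' @return List: `records` (data.frame: location_id, margin_distance_mean,
#'   tumor_pct, score, correct), `pearson_r`.
#' @export
misclassification_scatter <- function(scores, truth, threshold) {
  mal <- scores[scores$label == "malignant" & scores$context == "in_vivo", ]
  if (!nrow(mal)) {
    return(list(records = data.frame(), pearson_r = NA_real_))
  }
  agg <- stats::aggregate(score ~ location_id, data = mal, FUN = mean)
  idx <- match(agg$location_id, truth$location_id)
  records <- data.frame(
    location_id = agg$location_id,
    margin_distance_mean = truth$margin_distance_mean[idx],
    tumor_pct = truth$tumor_pct[idx],
    score = agg$score,
    correct = agg$score >= threshold,
    stringsAsFactors = FALSE)
  r <- if (nrow(records) >= 3L &&
           stats::sd(records$tumor_pct) > 0 &&
           stats::sd(records$margin_distance_mean) > 0) {
    stats::cor(records$tumor_pct, records$margin_distance_mean)
  } else {
    NA_real_
  }
  list(records = records, pearson_r = r)
}

#' Evaluate a cross-validation run
#'
#' Per model type: the iteration-level MCC (each iteration pools its folds'
#' test scores and is cut at its own MCC-optimal threshold), mean and SD
#' over iterations with a percentile CI; per-iteration AUC (mean, SD) and
#' the pooled-scores ROC/AUC; and two operating points on the pooled curve
#' -- the minimum-cost point and the MCC-optimal threshold -- with
#' iteration-level percentile CIs for sensitivity and specificity at the
#' cost-optimal point.
#'
#' @param cv A [run_cross_validation()] result.
#' @param truth Ground-truth data.frame (for the misclassification scatter).
#' @param cost_fp,cost_fn Misclassification costs for the operating point.
#' @param prevalence Prevalence for the cost criterion; `NULL` (default)
#'   uses the empirical malignant fraction of the scored locations.
#' @return Object of class `margin_eval`: list per model type with the
#'   metrics above plus the misclassification scatter at the MCC-optimal
#'   threshold.
#' @export
evaluate_cv <- function(cv, truth, cost_fp = 1, cost_fn = 1,
                        prevalence = NULL) {
  stopifnot(inherits(cv, "margin_cv"))
  scores <- cv$scores
  out <- list()
  for (mt in unique(scores$model_type)) {
    sm <- scores[scores$model_type == mt, ]
    iters <- sort(unique(sm$iteration))
    it_mcc <- it_auc <- it_sens <- it_spec <- rep(NA_real_, length(iters))
    for (i in seq_along(iters)) {
      si <- sm[sm$iteration == iters[i], ]
      if (length(unique(si$label)) < 2L) next
      opt <- mcc_optimal_threshold(si$score, si$label)
      it_mcc[i] <- opt$mcc
      curve <- roc_curve(si$score, si$label)
      it_auc[i] <- curve$auc
      prev_i <- mean(si$label == "malignant")
      op <- optimal_operating_point(curve, cost_fp, cost_fn,
                                    prevalence %||% prev_i)
      it_sens[i] <- op$sensitivity
      it_spec[i] <- op$specificity
    }
    ok <- !is.na(it_mcc)
    pooled <- roc_curve(sm$score, sm$label)
    prev <- prevalence %||% mean(sm$label == "malignant")
    op_pooled <- optimal_operating_point(pooled, cost_fp, cost_fn, prev)
    mcc_opt <- mcc_optimal_threshold(sm$score, sm$label)
    out[[mt]] <- list(
      model_type = mt,
      n_iterations = sum(ok),
      mcc = aggregate_iterations(it_mcc[ok]),
      auc = aggregate_iterations(it_auc[ok]),
      auc_pooled = pooled$auc,
      roc = pooled,
      operating_point = op_pooled,
      sensitivity = aggregate_iterations(it_sens[ok]),
      specificity = aggregate_iterations(it_spec[ok]),
      mcc_threshold = mcc_opt,
      scatter = misclassification_scatter(sm, truth, mcc_opt$threshold))
  }
  structure(out, class = "margin_eval")
}

#' Flatten an evaluation into a one-row-per-model report table
#'
#' @param ev A [evaluate_cv()] result.
#' @param regime Regime tag carried into the table.
#' @return data.frame with the headline metrics per model type.
#' @export
eval_report_table <- function(ev, regime = NA_character_) {
  stopifnot(inherits(ev, "margin_eval"))
  do.call(rbind, lapply(ev, function(e) data.frame(
    regime = regime, model_type = e$model_type,
    n_iterations = e$n_iterations,
    mcc_mean = e$mcc$mean, mcc_sd = e$mcc$sd,
    auc_mean = e$auc$mean, auc_pooled = e$auc_pooled,
    op_threshold = e$operating_point$threshold,
    sensitivity = e$sensitivity$mean,
    sensitivity_ci_lo = e$sensitivity$ci[1],
    sensitivity_ci_hi = e$sensitivity$ci[2],
    specificity = e$specificity$mean,
    specificity_ci_lo = e$specificity$ci[1],
    specificity_ci_hi = e$specificity$ci[2],
    mcc_opt_threshold = e$mcc_threshold$threshold,
    scatter_pearson_r = e$scatter$pearson_r,
    stringsAsFactors = FALSE)))
}
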