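# Experiment orchestration: resolved run configuration, stage execution in
# workflow order (simulate -> preprocess -> features -> select -> train ->
# evaluate), structured logging, and plain-text artifact I/O.

#' Build a resolved run configuration
#'
#' All tunables of a full experiment in one serializable list. Every field
#' has a default; overrides are supplied as nested lists. The configuration
#' hash carried on every report row makes runs traceable.
#'
#' @param simulation Overrides for [simulation_config()] fields.
#' @param cv List: `model_types`, `regimes`, `n_folds`, `n_iterations`.
#' @param mrmr List: `threshold`, `bins`, `scheme`, `max_features`.
#' @param features List: `sg_window`, `sg_order`, `stitch_policy`.
#' @param evaluation List: `cost_fp`, `cost_fn`.
#' @param seed Global seed; stage seeds derive from it.
#' @return Object of class `run_config`.
#' @export
run_config <- function(simulation = list(), cv = list(), mrmr = list(),
                       features = list(), evaluation = list(), seed = 1L) {
  cfg <- list(
    simulation = utils::modifyList(
      list(n_patients = 100L, locations_per_patient = 6L,
           tumor_location_rate = 0.10, in_vivo_proportion = 0.5,
           class_separation = 0.6), simulation),
    cv = utils::modifyList(
      list(model_types = c("linear_svm", "quadratic_svm", "weighted_knn",
                           "rusboost"),
           regimes = c("ex_vivo_only", "in_vivo_only", "both"),
           n_folds = 5L, n_iterations = 20L), cv),
    mrmr = utils::modifyList(
      list(threshold = 0.015, bins = 10L, scheme = "mid",
           max_features = 60L), mrmr),
    features = utils::modifyList(
      list(sg_window = 11L, sg_order = 2L, stitch_policy = "crossfade"),
      features),
    evaluation = utils::modifyList(list(cost_fp = 1, cost_fn = 1),
                                   evaluation),
    seed = as.integer(seed))
  bad_models <- setdiff(cfg$cv$model_types,
                        c("linear_svm", "quadratic_svm", "weighted_knn",
                          "rusboost"))
  if (length(bad_models)) {
    abort_input("unknown model type(s): %s", paste(bad_models, collapse = ", "))
  }
  bad_regimes <- setdiff(cfg$cv$regimes, .regimes)
  if (length(bad_regimes)) {
    abort_input("unknown regime(s): %s", paste(bad_regimes, collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

#' Hash of a resolved run configuration
#'
#' @param config A [run_config()].
#' @return Character hash.
#' @export
config_hash <- function(config) {
  rlang::hash(unclass(config))
}

#' Execute a full experiment
#'
#' Simulates the cohort, runs patient-grouped repeated cross-validation for
#' every model type under every training regime, evaluates, and writes the
#' run artifacts (resolved config as YAML, per-regime score tables and
#' feature selections, the report as CSV and JSON, pooled ROC points, and a
#' structured stage log) into `out_dir`. Re-running the same configuration
#' produces identical report files.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if absent); `NULL` skips
#'   writing.
#' @param cohort Optional pre-built cohort (skips simulation).
#' @return Invisibly, a list with `report` (data.frame), `evaluations`
#'   (nested per regime), `cohort`, and `config`.
#' @export
run_experiment <- function(config = run_config(), out_dir = NULL,
                           cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  log_lines <- character(0)
  log_stage <- function(stage, detail) {
    line <- sprintf("%s stage=%s seed=%d config=%s %s",
                    format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage,
                    config$seed, hash, detail)
    log_lines <<- c(log_lines, line)
  }

  if (is.null(cohort)) {
    sim_cfg <- do.call(simulation_config,
                       c(config$simulation, list(seed = config$seed)))
    cohort <- simulate_cohort(sim_cfg)
    log_stage("simulate", sprintf("locations=%d", nrow(cohort$truth)))
  } else {
    log_stage("simulate", "skipped (cohort supplied)")
  }

  reports <- list()
  evaluations <- list()
  for (regime in config$cv$regimes) {
    cv <- run_cross_validation(
      cohort,
      model_types = config$cv$model_types,
      regime = regime,
      n_folds = config$cv$n_folds,
      n_iterations = config$cv$n_iterations,
      seed = derive_seed(config$seed, paste0("cv-", regime)),
      mrmr_threshold = config$mrmr$threshold,
      mrmr_bins = config$mrmr$bins,
      mrmr_scheme = config$mrmr$scheme,
      mrmr_max_features = config$mrmr$max_features,
      sg_window = config$features$sg_window,
      sg_order = config$features$sg_order,
      stitch_policy = config$features$stitch_policy)
    n_train_invivo <- if (regime == "ex_vivo_only") {
      0L # regime contract: no in vivo location enters any fitted state
    } else {
      NA_integer_
    }
    log_stage("train", sprintf("regime=%s scored=%d", regime,
                               nrow(cv$scores)))
    ev <- evaluate_cv(cv, cohort$truth,
                      cost_fp = config$evaluation$cost_fp,
                      cost_fn = config$evaluation$cost_fn)
    log_stage("evaluate", sprintf("regime=%s models=%d", regime, length(ev)))
    tab <- eval_report_table(ev, regime = regime)
    tab$config_hash <- hash
    reports[[regime]] <- tab
    evaluations[[regime]] <- list(cv = cv, eval = ev)

    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      data.table::fwrite(cv$scores,
                         file.path(out_dir,
                                   sprintf("scores_%s.csv", regime)))
      if (!is.null(cv$selections)) {
        data.table::fwrite(cv$selections,
                           file.path(out_dir,
                                     sprintf("selections_%s.csv", regime)))
      }
      roc_rows <- do.call(rbind, lapply(ev, function(e) {
        data.frame(model_type = e$model_type,
                   threshold = e$roc$thresholds,
                   fpr = e$roc$fpr, tpr = e$roc$tpr,
                   stringsAsFactors = FALSE)
      }))
      write_roc_csv(roc_rows, file.path(out_dir,
                                        sprintf("roc_%s.csv", regime)))
    }
  }
  report <- do.call(rbind, reports)
  rownames(report) <- NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
    data.table::fwrite(report, file.path(out_dir, "report.csv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  invisible(list(report = report, evaluations = evaluations,
                 cohort = cohort, config = config))
}

# ---------------------------------------------------------------------------
# Plain-text artifact I/O with schema validation.

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort_input("%s: missing column(s) %s", what,
                paste(missing, collapse = ", "))
  }
}

#' Write raw measurements as long-format CSV
#'
#' Columns: patient_id, location_id, context, fiber, range, replicate,
#' wavelength_nm, intensity.
#'
#' @param measurements List of `raw_measurement` objects.
#' @param path Output CSV path.
#' @export
write_spectra_csv <- function(measurements, path) {
  rows <- lapply(measurements, function(m) {
    per_fiber <- lapply(1:5, function(f) {
      fib <- m$fibers[[f]]
      rbind(
        data.table::data.table(
          fiber = f, range = "vis",
          replicate = rep(1:3, each = length(fib$vis_wavelengths)),
          wavelength_nm = rep(fib$vis_wavelengths, times = 3),
          intensity = as.vector(t(fib$vis_replicates))),
        data.table::data.table(
          fiber = f, range = "nir",
          replicate = rep(1:3, each = length(fib$nir_wavelengths)),
          wavelength_nm = rep(fib$nir_wavelengths, times = 3),
          intensity = as.vector(t(fib$nir_replicates))))
    })
    dt <- data.table::rbindlist(per_fiber)
    dt[, `:=`(patient_id = m$patient_id, location_id = m$location_id,
              context = m$context)]
    dt
  })
  out <- data.table::rbindlist(rows)
  data.table::setcolorder(out, c("patient_id", "location_id", "context",
                                 "fiber", "range", "replicate",
                                 "wavelength_nm", "intensity"))
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read raw measurements from long-format CSV
#'
#' Validates the schema (column names, wavelength and intensity ranges,
#' fiber/replicate counts) and reconstructs `raw_measurement` objects.
#'
#' @param path CSV path written by [write_spectra_csv()].
#' @return List of `raw_measurement` objects.
#' @export
read_spectra_csv <- function(path) {
  dt <- data.table::fread(path)
  .require_columns(dt, c("patient_id", "location_id", "context", "fiber",
                         "range", "replicate", "wavelength_nm", "intensity"),
                   "spectra CSV")
  bad_wl <- which(dt$wavelength_nm < 200 | dt$wavelength_nm > 1750)
  if (length(bad_wl)) {
    abort_input("spectra CSV: wavelength_nm out of [200, 1750] at line %d",
                bad_wl[1] + 1L)
  }
  bad_int <- which(dt$intensity < 0)
  if (length(bad_int)) {
    abort_input("spectra CSV: negative intensity at line %d", bad_int[1] + 1L)
  }
  if (!all(dt$range %in% c("vis", "nir"))) {
    abort_input("spectra CSV: column range must be 'vis' or 'nir'")
  }
  loc_ids <- unique(dt$location_id)
  lapply(loc_ids, function(lid) {
    d <- dt[dt$location_id == lid, ]
    fibers <- lapply(sort(unique(d$fiber)), function(f) {
      df <- d[d$fiber == f, ]
      grab <- function(rng) {
        dr <- df[df$range == rng, ]
        wl <- sort(unique(dr$wavelength_nm))
        reps <- t(vapply(1:3, function(rep_i) {
          dd <- dr[dr$replicate == rep_i, ]
          dd$intensity[order(dd$wavelength_nm)]
        }, numeric(length(wl))))
        list(wavelengths = wl, replicates = reps)
      }
      vis <- grab("vis")
      nir <- grab("nir")
      list(vis_wavelengths = vis$wavelengths, vis_replicates = vis$replicates,
           nir_wavelengths = nir$wavelengths, nir_replicates = nir$replicates)
    })
    if (length(fibers) != 5L) {
      abort_input("spectra CSV: location %s has %d fibers (expected 5)",
                  lid, length(fibers))
    }
    structure(list(patient_id = d$patient_id[1], location_id = lid,
                   context = d$context[1], fibers = fibers),
              class = "raw_measurement")
  })
}

#' Write / read ground-truth CSV
#'
#' @param truth Ground-truth data.frame (see [simulate_cohort()]).
#' @param path CSV path.
#' @export
write_truth_csv <- function(truth, path) {
  data.table::fwrite(truth, path)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  .require_columns(df, c("location_id", "patient_id", "context", "label",
                         "tumor_pct", "fat_pct", "connective_pct",
                         "margin_distance_min", "margin_distance_central",
                         "margin_distance_max", "margin_distance_mean"),
                   "truth CSV")
  bad <- which(abs(df$tumor_pct + df$fat_pct + df$connective_pct - 100) >
                 1e-6)
  if (length(bad)) {
    abort_input("truth CSV: tissue percentages do not sum to 100 at line %d",
                bad[1] + 1L)
  }
  bad <- which((df$tumor_pct > 0) != (df$label == "malignant"))
  if (length(bad)) {
    abort_input("truth CSV: label inconsistent with tumor_pct at line %d",
                bad[1] + 1L)
  }
  df
}

#' Write a feature table / ROC points as CSV
#'
#' @param x data.frame to write.
#' @param path CSV path.
#' @export
write_features_csv <- function(x, path) {
  data.table::fwrite(x, path)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
write_roc_csv <- function(x, path) {
  data.table::fwrite(x, path)
  invisible(path)
}

#' Write a synthetic section to disk
#'
#' RGB PNG, indexed label-mask PNG and a JSON sidecar holding the ink
#' polyline and pixel size.
#'
#' @param section A [section_image()].
#' @param stem Output path stem; writes `<stem>_rgb.png`,
#'   `<stem>_mask.png`, `<stem>.json`.
#' @export
write_section <- function(section, stem) {
  stopifnot(inherits(section, "section_image"))
  png::writePNG(section$rgb / 255, paste0(stem, "_rgb.png"))
  png::writePNG(section$label_mask / 255, paste0(stem, "_mask.png"))
  jsonlite::write_json(
    list(ink_polyline = apply(section$ink_polyline, 1,
                              function(p) list(x = p[[1]], y = p[[2]])),
         pixel_size_um = section$pixel_size_um),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}
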