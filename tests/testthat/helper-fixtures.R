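# Shared fixtures, generated in code at test time.

# Small patient-clustered cohort; sizes chosen so every fold of a 5-fold
# patient partition still carries both classes.
tiny_cohort <- function(seed = 11, n_patients = 15, locations_per_patient = 4,
                        tumor_location_rate = 0.25, ...) {
  cfg <- simulation_config(n_patients = n_patients,
                           locations_per_patient = locations_per_patient,
                           tumor_location_rate = tumor_location_rate,
                           seed = seed, ...)
  simulate_cohort(cfg)
}

# Flat baseline with a Gaussian dip, on the 1200-sample analysis grid.
gaussian_dip_spectrum <- function(center = 1450, sigma = 30, depth = 0.3,
                                  baseline = 1) {
  wl <- seq(400, 1599)
  baseline - depth * exp(-(wl - center)^2 / (2 * sigma^2))
}

# One noiseless raw measurement with a fixed composition.
noiseless_measurement <- function(composition = NULL, seed = 5) {
  cfg <- simulation_config(gain_sd = 0, additive_sd = 0, path_jitter_sd = 0,
                           fiber_jitter_sd = 0, seed = seed)
  if (is.null(composition)) {
    composition <- tissue_composition(0.6, 0.22, 0.14, 0.04, 0.9)
  }
  withr::with_seed(seed, simulate_measurement(composition, cfg))
}

# Independent plug-in MI (bits) from a base-R contingency table.
oracle_mi <- function(x, y) {
  tab <- table(x, y) / length(x)
  px <- rowSums(tab)
  py <- colSums(tab)
  s <- 0
  for (i in seq_along(px)) {
    for (j in seq_along(py)) {
      if (tab[i, j] > 0) s <- s + tab[i, j] * log2(tab[i, j] / (px[i] * py[j]))
    }
  }
  s
}

# Independent greedy MRMR (MID scheme) over pre-discretized columns.
oracle_mrmr <- function(X, y, bins = 10) {
  disc <- lapply(seq_len(ncol(X)), function(j) discretize_ef(X[, j], bins))
  p <- ncol(X)
  relevance <- vapply(disc, function(d) oracle_mi(d, y), numeric(1))
  sel <- integer(0)
  scores <- numeric(0)
  remaining <- seq_len(p)
  while (length(remaining)) {
    crit <- vapply(remaining, function(j) {
      if (!length(sel)) return(relevance[j])
      relevance[j] - mean(vapply(sel, function(s) {
        oracle_mi(disc[[j]], disc[[s]])
      }, numeric(1)))
    }, numeric(1))
    k <- which.max(crit)
    scores <- c(scores, crit[k])
    sel <- c(sel, remaining[k])
    remaining <- remaining[-k]
  }
  list(order = sel, scores = scores)
}
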