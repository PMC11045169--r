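test_that("composition draws close to 1, separate the classes and are deterministic", {
  set.seed(42)
  healthy <- replicate(2000, sample_composition("healthy", "in_vivo"),
                       simplify = FALSE)
  tumor <- replicate(2000, sample_composition("tumor", "in_vivo"),
                     simplify = FALSE)
  sums <- vapply(c(healthy, tumor), function(cc) sum(cc$fractions), numeric(1))
  expect_true(all(abs(sums - 1) < 1e-9))
  fat_h <- mean(vapply(healthy, function(cc) cc$fractions[["fat"]], numeric(1)))
  fat_t <- mean(vapply(tumor, function(cc) cc$fractions[["fat"]], numeric(1)))
  expect_gt(fat_h, fat_t)

  a <- withr::with_seed(7, sample_composition("tumor", "ex_vivo"))
  b <- withr::with_seed(7, sample_composition("tumor", "ex_vivo"))
  expect_identical(a, b)
})

test_that("oxygen saturation reflects the measurement context", {
  set.seed(1)
  sat_iv <- replicate(200, sample_composition("healthy", "in_vivo")$oxygen_saturation)
  sat_ev <- replicate(200, sample_composition("healthy", "ex_vivo")$oxygen_saturation)
  expect_gt(min(sat_iv), max(sat_ev))
})

test_that("noiseless replicates are identical and zero absorption gives unit reflectance", {
  m <- noiseless_measurement()
  for (f in 1:5) {
    expect_equal(m$fibers[[f]]$vis_replicates[1, ],
                 m$fibers[[f]]$vis_replicates[3, ])
    expect_equal(m$fibers[[f]]$nir_replicates[1, ],
                 m$fibers[[f]]$nir_replicates[2, ])
  }

  cfg <- simulation_config(gain_sd = 0, additive_sd = 0, path_jitter_sd = 0,
                           fiber_jitter_sd = 0)
  comp <- tissue_composition(0.5, 0.3, 0.15, 0.05, 0.8)
  zero <- list(vis = matrix(0, length(drsmargin:::VIS_GRID), 5),
               nir = matrix(0, length(drsmargin:::NIR_GRID), 5))
  m0 <- simulate_measurement(comp, cfg, absorbers = zero)
  expect_equal(unique(as.vector(m0$fibers[[1]]$vis_replicates)), 1)
  expect_equal(unique(as.vector(m0$fibers[[3]]$nir_replicates)), 1)
})

test_that("class-mean spectra differ most near the fat and water NIR bands", {
  cfg <- simulation_config(gain_sd = 0, additive_sd = 0, path_jitter_sd = 0,
                           fiber_jitter_sd = 0)
  mean_spectrum <- function(class_label) {
    withr::with_seed(101, {
      specs <- replicate(200, {
        comp <- sample_composition(class_label, "in_vivo")
        m <- simulate_measurement(comp, cfg)
        preprocess_measurement(m)[1, ]
      })
      rowMeans(specs)
    })
  }
  diff <- abs(mean_spectrum("tumor") - mean_spectrum("healthy"))
  wl <- seq(400, 1599)
  nir <- wl >= 900
  peak_wl <- wl[nir][which.max(diff[nir])]
  expect_true(abs(peak_wl - 1210) <= 60 || abs(peak_wl - 1450) <= 60)
})

test_that("cohorts are byte-identical under the same seed", {
  cfg <- simulation_config(n_patients = 8, locations_per_patient = 3, seed = 1)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
})

test_that("cohort structure matches the configured rates and invariants", {
  cfg <- simulation_config(n_patients = 334, locations_per_patient = 6,
                           tumor_location_rate = 0.10, seed = 2)
  truth <- simulate_cohort(cfg)$truth
  expect_equal(nrow(truth), 2004)
  frac <- mean(truth$label == "malignant")
  expect_gte(frac, 0.08)
  expect_lte(frac, 0.12)

  expect_identical(truth$label == "malignant", truth$tumor_pct > 0)
  expect_equal(truth$tumor_pct + truth$fat_pct + truth$connective_pct,
               rep(100, nrow(truth)), tolerance = 1e-9)

  mal <- truth[truth$label == "malignant", ]
  expect_equal(mal$margin_distance_mean,
               (mal$margin_distance_min + mal$margin_distance_central +
                  mal$margin_distance_max) / 3)
  expect_lt(cor(mal$tumor_pct, mal$margin_distance_mean), 0)

  healthy <- truth[truth$label == "healthy", ]
  expect_true(all(is.na(healthy$margin_distance_mean)))
})

test_that("extremity noise is inflated relative to the mid-range", {
  cfg <- simulation_config(gain_sd = 0, additive_sd = 0.002,
                           extremity_factor = 10, path_jitter_sd = 0,
                           fiber_jitter_sd = 0, seed = 3)
  comp <- tissue_composition(0.6, 0.22, 0.14, 0.04, 0.9)
  set.seed(9)
  reps <- replicate(50, {
    m <- simulate_measurement(comp, cfg)
    m$fibers[[1]]$vis_replicates[1, ]
  })
  wl <- drsmargin:::VIS_GRID
  noise_sd <- apply(reps, 1, sd)
  extremity <- wl >= 350 & wl <= 400
  middle <- wl >= 500 & wl <= 1100
  expect_gt(mean(noise_sd[extremity]), 4 * mean(noise_sd[middle]))
})
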