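test_that("replicate averaging is the pointwise mean", {
  s <- sin(seq(0, 3, length.out = 50)) + 2
  expect_equal(average_replicates(rbind(s, s, s)), s,
               ignore_attr = TRUE)
  expect_equal(average_replicates(rbind(rep(1, 10), rep(2, 10), rep(3, 10))),
               rep(2, 10))
  set.seed(4)
  reps <- matrix(runif(3 * 40), nrow = 3)
  brute <- vapply(1:40, function(j) mean(reps[, j]), numeric(1))
  expect_equal(average_replicates(reps), brute)
  expect_error(average_replicates(list(1:5, 1:6)), "different grids")
})

test_that("stitching crossfades the overlap and resamples both ranges", {
  vis_wl <- seq(200, 1160, by = 2)
  nir_wl <- seq(900, 1750, by = 3)

  st <- stitch_ranges(vis_wl, rep(0.5, length(vis_wl)),
                      nir_wl, rep(0.5, length(nir_wl)))
  expect_equal(st$wavelengths, seq(200, 1750))
  expect_equal(st$intensities, rep(0.5, length(st$wavelengths)))

  st2 <- stitch_ranges(vis_wl, rep(1, length(vis_wl)),
                       nir_wl, rep(0, length(nir_wl)))
  expect_equal(st2$intensities[st2$wavelengths == 900], 1.0)
  expect_equal(st2$intensities[st2$wavelengths == 1160], 0.0)
  expect_equal(st2$intensities[st2$wavelengths == 1030], 0.5)

  # independent resample-then-blend oracle on piecewise-linear inputs
  vis <- 0.001 * vis_wl + 0.2
  nir <- -0.0005 * nir_wl + 2
  st3 <- stitch_ranges(vis_wl, vis, nir_wl, nir)
  grid <- seq(200, 1750)
  vis_r <- approx(vis_wl, vis, xout = grid, rule = 2)$y
  nir_r <- approx(nir_wl, nir, xout = grid, rule = 2)$y
  w <- pmin(1, pmax(0, (1160 - grid) / (1160 - 900)))
  oracle <- ifelse(grid < 900, vis_r,
                   ifelse(grid > 1160, nir_r, w * vis_r + (1 - w) * nir_r))
  expect_equal(st3$intensities, oracle, tolerance = 1e-12)

  expect_error(stitch_ranges(seq(200, 800), rep(1, 601),
                             seq(900, 1750), rep(1, 851)),
               "overlap")
})

test_that("trimming keeps exactly the 1200 analysis wavelengths", {
  grid <- seq(200, 1750)
  st <- list(wavelengths = grid, intensities = 0.001 * grid)
  tr <- trim_spectrum(st$wavelengths, st$intensities)
  expect_length(tr$intensities, 1200)
  expect_equal(tr$wavelengths[1], 400)
  expect_equal(tr$wavelengths[1200], 1599)
  tr2 <- trim_spectrum(tr$wavelengths, tr$intensities)
  expect_identical(tr, tr2)
  expect_error(trim_spectrum(seq(500, 1599), rep(1, 1100)), "cover")
})

test_that("preprocessing a measurement yields five 1200-sample spectra", {
  m <- noiseless_measurement()
  sp <- preprocess_measurement(m)
  expect_equal(dim(sp), c(5, 1200))
  expect_true(all(is.finite(sp)))
  m$fibers <- m$fibers[1:4]
  expect_error(preprocess_measurement(m), "5 fibers")
})

test_that("MSC reference is the training mean and corrects affine distortion", {
  ref <- fit_msc_reference(rbind(rep(0, 1200), rep(2, 1200)))
  expect_equal(ref$mean_intensities, rep(1, 1200))
  expect_equal(ref$n_contributing, 2L)
  expect_error(fit_msc_reference(matrix(1, 1, 1200)), ">= 2")
  s <- gaussian_dip_spectrum()
  expect_equal(fit_msc_reference(matrix(s, 1, 1200, byrow = TRUE),
                                 allow_single = TRUE)$mean_intensities, s)
  set.seed(8)
  specs <- t(replicate(6, gaussian_dip_spectrum() + rnorm(1200, 0, 0.01)))
  brute <- vapply(1:1200, function(j) mean(specs[, j]), numeric(1))
  expect_equal(fit_msc_reference(specs)$mean_intensities, brute)

  m <- gaussian_dip_spectrum()
  ref2 <- fit_msc_reference(rbind(m, m + 0.01), allow_single = FALSE)
  # x = 3 + 2 m is an exact affine image of the reference mean (m + 0.005),
  # so correction recovers the reference mean itself
  corrected <- msc_normalize(3 + 2 * m, ref2)
  expect_equal(corrected, ref2$mean_intensities, tolerance = 1e-12)
  # exact inversion when the reference is m itself
  ref_m <- fit_msc_reference(matrix(m, 1, 1200, byrow = TRUE),
                             allow_single = TRUE)
  expect_equal(msc_normalize(3 + 2 * m, ref_m), m, tolerance = 1e-12)
  expect_equal(msc_normalize(m, ref_m), m, tolerance = 1e-12)
})

test_that("MSC refit of a corrected spectrum has intercept 0 and slope 1", {
  m <- gaussian_dip_spectrum()
  ref <- fit_msc_reference(matrix(m, 1, 1200, byrow = TRUE),
                           allow_single = TRUE)
  set.seed(2)
  x <- m + rnorm(1200, 0, 0.02)
  corrected <- msc_normalize(x, ref)
  fit <- lm(corrected ~ m)
  expect_equal(unname(coef(fit)), c(0, 1), tolerance = 1e-9)
  # idempotence
  expect_equal(msc_normalize(corrected, ref), corrected, tolerance = 1e-9)
})

test_that("MSC rejects degenerate inputs", {
  m <- gaussian_dip_spectrum()
  ref <- fit_msc_reference(matrix(m, 1, 1200, byrow = TRUE),
                           allow_single = TRUE)
  expect_error(msc_normalize(rep(1, 1200), ref), "degenerate")
  flat_ref <- fit_msc_reference(rbind(rep(1, 1200), rep(1, 1200)))
  expect_error(msc_normalize(m, flat_ref), "constant")
})
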