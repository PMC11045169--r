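wl <- seq(400, 1599)

test_that("chord slope follows the quartile maxima", {
  expect_equal(chord_slope(rep(1, 1200), 1000, 1200)$slope, 0)

  lin <- 0.001 * wl
  ch <- chord_slope(lin, 1021, 1102)
  # strictly increasing spectrum: argmaxes sit at the right edges of the
  # first and last quarter
  expect_equal(ch$lambda1, 1021 + floor((1102 - 1021) / 4))
  expect_equal(ch$lambda2, 1102)
  expect_equal(ch$slope, 0.001, tolerance = 1e-12)

  dip <- gaussian_dip_spectrum(center = 1250, sigma = 20)
  ch2 <- chord_slope(dip, 1200, 1300)
  expect_equal(ch2$slope, 0, tolerance = 1e-9)

  expect_error(chord_slope(rep(1, 1200), 1500, 1601), "outside")
})

test_that("chord deficit finds the dip depth and location", {
  lin <- 0.002 * wl + 1
  ch <- chord_slope(lin, 1142, 1225)
  expect_equal(chord_deficit(lin, ch)$max_diff, 0, tolerance = 1e-12)

  dip <- gaussian_dip_spectrum(center = 1450, sigma = 30, depth = 0.3)
  ch2 <- chord_slope(dip, 1382, 1574)
  de <- chord_deficit(dip, ch2)
  # closed-form oracle: evaluate chord minus Gaussian on a fine grid
  g <- function(l) 1 - 0.3 * exp(-(l - 1450)^2 / (2 * 30^2))
  fine <- seq(ch2$lambda1, ch2$lambda2, by = 0.01)
  chord_line <- g(ch2$lambda1) + ch2$slope * (fine - ch2$lambda1)
  oracle <- chord_line - g(fine)
  expect_equal(de$max_diff, max(oracle), tolerance = 0.01 * max(oracle))
  expect_lte(abs(de$lambda_max_diff - fine[which.max(oracle)]), 2)

  # two equal dips: the smaller wavelength wins the tie
  twin <- rep(1, 1200)
  twin[wl == 1440] <- 0.7
  twin[wl == 1480] <- 0.7
  ch3 <- chord_slope(twin, 1404, 1502)
  expect_equal(chord_deficit(twin, ch3)$lambda_max_diff, 1440)
})

test_that("inflection points bracket a Gaussian dip at center +/- sigma", {
  for (sigma in c(20, 30)) {
    dip <- gaussian_dip_spectrum(center = 1450, sigma = sigma)
    ch <- chord_slope(dip, 1382, 1574)
    de <- chord_deficit(dip, ch)
    fl <- inflection_points(dip, 1382, 1574, de$lambda_max_diff)
    expect_false(fl$clamped_left)
    expect_false(fl$clamped_right)
    expect_lte(abs(fl$lambda_left - (1450 - sigma)), 2)
    expect_lte(abs(fl$lambda_right - (1450 + sigma)), 2)
    expect_lte(fl$lambda_left, de$lambda_max_diff)
    expect_gte(fl$lambda_right, de$lambda_max_diff)
  }

  lin <- 0.001 * wl
  fl2 <- inflection_points(lin, 1021, 1102, 1060)
  expect_true(fl2$clamped_left && fl2$clamped_right)
  expect_equal(fl2$lambda_left, 1021)
  expect_equal(fl2$lambda_right, 1102)
})

test_that("a five-fiber measurement yields 400 deterministic features", {
  m <- noiseless_measurement()
  sp <- preprocess_measurement(m)
  fv <- extract_features(sp)
  expect_length(fv, 400)
  expect_identical(fv, extract_features(sp))

  ranges <- default_feature_ranges()
  expect_equal(nrow(ranges), 16)
  one_fiber <- vapply(seq_len(nrow(ranges)), function(r) {
    drsmargin:::extract_range_features(sp[1, ], ranges$lo[r], ranges$hi[r])
  }, numeric(5))
  expect_equal(length(one_fiber), 80)

  same <- sp[rep(1, 5), ]
  fv_same <- extract_features(same)
  blocks <- matrix(fv_same, ncol = 5)
  for (f in 2:5) expect_equal(blocks[, f], blocks[, 1])

  expect_error(extract_features(sp[1:4, ]), "5 x")
})

test_that("features are translation invariant and scale equivariant", {
  m <- noiseless_measurement()
  sp <- preprocess_measurement(m)
  fv <- extract_features(sp)
  op <- sub(".*\\.", "", names(fv))
  amp <- op %in% c("slope", "max_diff")

  shifted <- extract_features(sp + 0.37)
  expect_equal(shifted, fv, tolerance = 1e-9)

  scaled <- extract_features(sp * 3)
  expect_equal(scaled[amp], 3 * fv[amp], tolerance = 1e-9)
  expect_equal(scaled[!amp], fv[!amp], tolerance = 1e-9)
})

test_that("MSC-then-extract equals the amplitude-rescaled raw features", {
  # the per-fold fast path relies on this algebra
  m <- noiseless_measurement()
  sp <- preprocess_measurement(m)
  set.seed(3)
  ref <- fit_msc_reference(sp + matrix(rnorm(5 * 1200, 0, 0.01), 5))
  direct <- extract_features(msc_normalize(sp, ref))
  raw <- extract_features(sp)
  mc <- ref$mean_intensities - mean(ref$mean_intensities)
  b <- as.vector(sp %*% mc) / sum(mc^2)
  op <- sub(".*\\.", "", names(raw))
  fiber <- as.integer(sub("^f(\\d)\\..*", "\\1", names(raw)))
  rescaled <- raw
  amp <- op %in% c("slope", "max_diff")
  rescaled[amp] <- raw[amp] / b[fiber[amp]]
  expect_equal(rescaled, direct, tolerance = 1e-9)
})
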