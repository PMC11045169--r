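# Spectral preprocessing: replicate averaging, range stitching, extremity
# trimming and multiplicative scatter correction (MSC).
#
# Fixed pipeline order: average -> stitch -> trim -> MSC. The analysis grid
# is the uniform 1 nm grid over the half-open window [400, 1600) nm, i.e.
# samples at 400, 401, ..., 1599 nm -- 1200 wavelengths.

#' Average three replicate spectra
#'
#' @param replicates Numeric matrix, one replicate per row, or a list of
#'   equal-length numeric vectors on a common wavelength grid.
#' @return Pointwise arithmetic mean (numeric vector).
#' @export
average_replicates <- function(replicates) {
  if (is.list(replicates)) {
    n <- lengths(replicates)
    if (length(unique(n)) != 1L) {
      abort_input("replicates are on different grids (lengths %s)",
                  paste(unique(n), collapse = ", "))
    }
    replicates <- do.call(rbind, replicates)
  }
  stopifnot(is.matrix(replicates))
  colMeans(replicates)
}

#' Stitch visible and near-infrared spectra onto a common 1 nm grid
#'
#' Both input ranges are resampled to the uniform 1 nm grid 200-1750 nm by
#' linear interpolation. In the spectrometer overlap `[900, 1160]` nm the
#' output is a linear crossfade from full visible weight at 900 nm to full
#' near-infrared weight at 1160 nm (policy `"crossfade"`); outside the
#' overlap the covering range is used verbatim. Policies `"vis_priority"`
#' and `"nir_priority"` instead switch ranges at the overlap edge.
#'
#' @param vis_wavelengths,vis Visible-range grid (nm) and intensities.
#' @param nir_wavelengths,nir Near-infrared grid (nm) and intensities.
#' @param policy Overlap handling policy.
#' @return List with `wavelengths` (200:1750) and `intensities`.
#' @export
stitch_ranges <- function(vis_wavelengths, vis, nir_wavelengths, nir,
                          policy = c("crossfade", "vis_priority",
                                     "nir_priority")) {
  policy <- match.arg(policy)
  if (!length(vis) || !length(nir)) abort_input("empty input spectrum")
  stopifnot(length(vis_wavelengths) == length(vis),
            length(nir_wavelengths) == length(nir))
  lo <- max(min(vis_wavelengths), min(nir_wavelengths))
  hi <- min(max(vis_wavelengths), max(nir_wavelengths))
  if (lo >= hi) abort_input("spectrometer ranges do not overlap")

  grid <- STITCH_GRID
  vis_i <- stats::approx(vis_wavelengths, vis, xout = grid, rule = 2)$y
  nir_i <- stats::approx(nir_wavelengths, nir, xout = grid, rule = 2)$y
  vis_cov <- grid >= min(vis_wavelengths) & grid <= max(vis_wavelengths)
  nir_cov <- grid >= min(nir_wavelengths) & grid <= max(nir_wavelengths)

  out <- numeric(length(grid))
  both <- vis_cov & nir_cov
  out[vis_cov & !nir_cov] <- vis_i[vis_cov & !nir_cov]
  out[nir_cov & !vis_cov] <- nir_i[nir_cov & !vis_cov]
  # grid points beyond both instrument grids take the nearer range's
  # constant extension (can happen when a grid ends between 1 nm samples)
  uncov <- !vis_cov & !nir_cov
  out[uncov] <- ifelse(grid[uncov] < lo, vis_i[uncov], nir_i[uncov])
  if (any(both)) {
    w <- switch(policy,
      crossfade = (hi - grid[both]) / (hi - lo),
      vis_priority = 1,
      nir_priority = 0)
    out[both] <- w * vis_i[both] + (1 - w) * nir_i[both]
  }
  list(wavelengths = grid, intensities = out)
}

#' Trim a stitched spectrum to the analysis window
#'
#' Removes the noisy extremities (everything below 400 nm and at or above
#' 1600 nm), retaining exactly the 1200 samples at 400, 401, ..., 1599 nm.
#' Idempotent on an already-trimmed spectrum.
#'
#' @param wavelengths,intensities Spectrum on a grid covering `[400, 1600)`
#'   with 1 nm spacing (e.g. the output of [stitch_ranges()]).
#' @return List with `wavelengths` (400:1599, length 1200) and `intensities`.
#' @export
trim_spectrum <- function(wavelengths, intensities) {
  stopifnot(length(wavelengths) == length(intensities))
  idx <- match(ANALYSIS_GRID, wavelengths)
  if (anyNA(idx)) {
    abort_input("input grid does not cover the 400-1599 nm analysis window")
  }
  list(wavelengths = ANALYSIS_GRID, intensities = intensities[idx])
}

#' Fit an MSC reference spectrum
#'
#' The reference is the pointwise mean of the provided spectra. Under
#' cross-validation this must be the training-fold spectra only; the fitted
#' reference is frozen into the model artifact and applied to test spectra.
#'
#' @param spectra Numeric matrix (one spectrum per row, columns on the
#'   analysis grid) or a list of equal-length vectors.
#' @param allow_single Allow a single-spectrum reference (degenerate mean).
#' @return Object of class `msc_reference`: `wavelengths`,
#'   `mean_intensities`, `n_contributing`.
#' @export
fit_msc_reference <- function(spectra, allow_single = FALSE) {
  if (is.list(spectra)) spectra <- do.call(rbind, spectra)
  if (is.null(spectra) || !nrow(spectra)) abort_input("no spectra supplied")
  if (nrow(spectra) < 2L && !allow_single) {
    abort_input("MSC reference needs >= 2 spectra (or allow_single = TRUE)")
  }
  if (ncol(spectra) != length(ANALYSIS_GRID)) {
    abort_input("spectra must be on the 1200-sample analysis grid")
  }
  structure(list(wavelengths = ANALYSIS_GRID,
                 mean_intensities = colMeans(spectra),
                 n_contributing = nrow(spectra)),
            class = "msc_reference")
}

#' Multiplicative scatter correction
#'
#' Fits the affine scatter model `x ~ a + b * m` against the reference mean
#' spectrum `m` by ordinary least squares over all 1200 wavelengths and
#' returns the corrected spectrum `(x - a) / b`. Inverts multiplicative
#' path-length and additive offset distortions exactly; idempotent.
#'
#' @param intensities Spectrum on the analysis grid (vector), or a matrix of
#'   spectra (one per row) corrected column-wise in one call.
#' @param reference An [fit_msc_reference()] object.
#' @param slope_tol Slopes with `|b|` below this are rejected as degenerate.
#' @return Corrected spectrum, same shape as `intensities`.
#' @export
msc_normalize <- function(intensities, reference, slope_tol = 1e-8) {
  stopifnot(inherits(reference, "msc_reference"))
  m <- reference$mean_intensities
  if (stats::var(m) == 0) abort_input("MSC reference is constant")
  one_spectrum <- !is.matrix(intensities)
  x <- if (one_spectrum) matrix(intensities, nrow = 1L) else intensities
  if (ncol(x) != length(m)) abort_input("spectrum grid mismatch with reference")
  mc <- m - mean(m)
  b <- as.vector(x %*% mc) / sum(mc^2) # OLS slope per spectrum
  a <- rowMeans(x) - b * mean(m)
  if (any(abs(b) < slope_tol)) {
    abort_input("degenerate spectrum: |MSC slope| < %g", slope_tol)
  }
  out <- (x - a) / b
  if (one_spectrum) as.vector(out) else out
}

#' Preprocess one raw measurement to five analysis spectra
#'
#' Applies, per fiber: replicate averaging, stitching of the two
#' spectrometer ranges, and trimming to the 1200-sample analysis grid. MSC
#' is deliberately not applied here: the reference must come from training
#' data only, so normalization happens at model-fitting time.
#'
#' @param measurement A `raw_measurement`.
#' @param stitch_policy Overlap policy passed to [stitch_ranges()].
#' @return A 5 x 1200 matrix, one trimmed (un-normalized) spectrum per fiber,
#'   with attributes `location_id`, `patient_id`, `context`.
#' @export
preprocess_measurement <- function(measurement, stitch_policy = "crossfade") {
  stopifnot(inherits(measurement, "raw_measurement"))
  if (length(measurement$fibers) != 5L) {
    abort_input("measurement must have exactly 5 fibers (got %d)",
                length(measurement$fibers))
  }
  out <- matrix(NA_real_, nrow = 5L, ncol = length(ANALYSIS_GRID))
  for (f in 1:5) {
    fib <- measurement$fibers[[f]]
    if (nrow(fib$vis_replicates) != 3L || nrow(fib$nir_replicates) != 3L) {
      abort_input("fiber %d must have exactly 3 replicates per range", f)
    }
    vis <- average_replicates(fib$vis_replicates)
    nir <- average_replicates(fib$nir_replicates)
    st <- stitch_ranges(fib$vis_wavelengths, vis, fib$nir_wavelengths, nir,
                        policy = stitch_policy)
    out[f, ] <- trim_spectrum(st$wavelengths, st$intensities)$intensities
  }
  attr(out, "location_id") <- measurement$location_id
  attr(out, "patient_id") <- measurement$patient_id
  attr(out, "context") <- measurement$context
  out
}

#' Preprocess a whole cohort
#'
#' @param measurements List of `raw_measurement` objects.
#' @param stitch_policy Overlap policy passed to [stitch_ranges()].
#' @return List with `spectra` (a `5 * n_locations` x 1200 matrix, fibers of
#'   one location in consecutive rows) and `index` (data.frame: location_id,
#'   patient_id, context, fiber, row).
#' @export
preprocess_cohort <- function(measurements, stitch_policy = "crossfade") {
  mats <- lapply(measurements, preprocess_measurement,
                 stitch_policy = stitch_policy)
  spectra <- do.call(rbind, mats)
  index <- data.frame(
    location_id = rep(vapply(measurements, `[[`, "", "location_id"), each = 5L),
    patient_id = rep(vapply(measurements, `[[`, "", "patient_id"), each = 5L),
    context = rep(vapply(measurements, `[[`, "", "context"), each = 5L),
    fiber = rep(1:5, times = length(measurements)),
    row = seq_len(nrow(spectra)),
    stringsAsFactors = FALSE)
  list(spectra = spectra, index = index)
}
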