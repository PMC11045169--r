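# Chord-based spectral feature extraction.
#
# For each wavelength range, five operators are evaluated on the normalized
# spectrum: (1) the slope of the chord through the intensity maxima of the
# first and last quarter of the range, (2) the maximum deficit of the
# spectrum below that chord, (3) the wavelength of that maximum deficit, and
# (4, 5) the inflection points left and right of it. With the default 16
# ranges this yields 80 features per fiber and 400 per five-fiber
# measurement.

#' Default wavelength-range set
#'
#' The 16 distinct near-infrared ranges over which the five chord operators
#' are evaluated. These ranges bracket the fat, water and collagen
#' absorption dips that discriminate tumor from healthy breast tissue. The
#' set is configuration, not a constant: any data.frame with columns
#' `lo`, `hi`, `name` (each range within 400-1599 nm, >= 8 grid samples)
#' can be passed to the extraction functions.
#'
#' @return data.frame with columns `lo`, `hi` (nm) and `name`.
#' @export
default_feature_ranges <- function() {
  lo <- c(1213, 931, 1224, 1142, 1021, 999, 1395, 1404,
          1467, 1121, 932, 1112, 1201, 1382, 883, 926)
  hi <- c(1248, 1195, 1331, 1225, 1102, 1034, 1430, 1437,
          1502, 1401, 967, 1147, 1236, 1574, 1149, 1149)
  data.frame(lo = lo, hi = hi, name = sprintf("r%d_%d", lo, hi),
             stringsAsFactors = FALSE)
}

.range_indices <- function(wavelengths, lo, hi) {
  if (lo < wavelengths[1] || hi > wavelengths[length(wavelengths)]) {
    abort_input("range [%g, %g] outside the spectrum grid", lo, hi)
  }
  which(wavelengths >= lo & wavelengths <= hi)
}

#' Chord slope over a wavelength range
#'
#' The chord runs through the intensity maxima of the first and last
#' quarter of the range (quarters defined by wavelength span); ties in the
#' argmax take the smaller wavelength. The slope is
#' `(I(l2) - I(l1)) / (l2 - l1)` in intensity per nm.
#'
#' @param intensities Spectrum intensities.
#' @param lo,hi Range bounds (nm), within the spectrum grid.
#' @param wavelengths Spectrum grid (nm), default the analysis grid.
#' @return List: `slope`, `lambda1`, `lambda2`, `i1`, `i2` (grid indices of
#'   the chord endpoints).
#' @export
chord_slope <- function(intensities, lo, hi, wavelengths = ANALYSIS_GRID) {
  idx <- .range_indices(wavelengths, lo, hi)
  if (length(idx) < 8L) abort_input("range must contain >= 8 grid samples")
  wl <- wavelengths[idx]
  q <- (hi - lo) / 4
  first_q <- idx[wl <= lo + q]
  last_q <- idx[wl >= hi - q]
  i1 <- first_q[which.max(intensities[first_q])]
  i2 <- last_q[which.max(intensities[last_q])]
  if (wavelengths[i2] == wavelengths[i1]) {
    abort_input("degenerate range: chord endpoints coincide")
  }
  list(slope = (intensities[i2] - intensities[i1]) /
         (wavelengths[i2] - wavelengths[i1]),
       lambda1 = wavelengths[i1], lambda2 = wavelengths[i2],
       i1 = i1, i2 = i2)
}

#' Maximum deficit of the spectrum below its chord
#'
#' Evaluates `chord_line(lambda) - I(lambda)` between the chord endpoints
#' and returns the maximum and its wavelength (first occurrence on ties,
#' scanning in ascending wavelength). Absorption dips sit below their chord,
#' so the deficit is positive at a dip.
#'
#' @param intensities,wavelengths Spectrum.
#' @param chord Result of [chord_slope()] on the same spectrum and range.
#' @return List: `max_diff`, `lambda_max_diff`, `i_max` (grid index).
#' @export
chord_deficit <- function(intensities, chord, wavelengths = ANALYSIS_GRID) {
  seg <- chord$i1:chord$i2
  line <- intensities[chord$i1] +
    chord$slope * (wavelengths[seg] - chord$lambda1)
  diff <- line - intensities[seg]
  k <- which.max(diff)
  list(max_diff = diff[k], lambda_max_diff = wavelengths[seg[k]],
       i_max = seg[k])
}

# Second derivative of the Savitzky-Golay-smoothed spectrum, one value per
# grid sample. The grid spacing is 1 nm, so units are intensity / nm^2.
sg_second_derivative <- function(intensities, window = 11L, order = 2L) {
  n <- length(intensities)
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  window <- min(window, if (n %% 2L == 1L) n else n - 1L)
  signal::sgolayfilt(intensities, p = order, n = window, m = 2L)
}

#' Inflection points around the maximum-deficit wavelength
#'
#' Scans the second derivative of the Savitzky-Golay-smoothed spectrum
#' outward from `lambda_max_diff`; the nearest sign change on each side
#' gives the inflection wavelength by linear interpolation of the zero
#' crossing. If no crossing occurs before the range edge, the edge is
#' returned with the corresponding `clamped` flag set.
#'
#' @param intensities,wavelengths Spectrum.
#' @param lo,hi Range bounds (nm).
#' @param lambda_max_diff Wavelength of the maximum chord deficit.
#' @param sg_window,sg_order Savitzky-Golay smoothing window (samples, odd)
#'   and polynomial order.
#' @param d2 Optional precomputed full-spectrum second derivative (internal
#'   fast path).
#' @return List: `lambda_left`, `lambda_right`, `clamped_left`,
#'   `clamped_right`.
#' @export
inflection_points <- function(intensities, lo, hi, lambda_max_diff,
                              wavelengths = ANALYSIS_GRID,
                              sg_window = 11L, sg_order = 2L, d2 = NULL) {
  idx <- .range_indices(wavelengths, lo, hi)
  if (is.null(d2)) d2 <- sg_second_derivative(intensities, sg_window, sg_order)
  i0 <- which.min(abs(wavelengths - lambda_max_diff))
  if (lambda_max_diff < lo || lambda_max_diff > hi) {
    abort_input("lambda_max_diff outside the range")
  }
  i_lo <- idx[1]
  i_hi <- idx[length(idx)]

  # curvature below this is treated as zero, so straight segments (whose
  # second derivative is numerical noise) produce no spurious crossings;
  # the threshold is relative to the spectrum's own intensity scale
  z_tol <- 1e-8 * max(abs(intensities[idx]), 1e-12)
  zsig <- function(v) if (abs(v) <= z_tol) 0 else sign(v)
  scan <- function(step, stop_at) {
    last_j <- i0
    last_s <- zsig(d2[i0])
    j <- i0 + step
    while (if (step < 0L) j >= stop_at else j <= stop_at) {
      s <- zsig(d2[j])
      if (s != 0) {
        if (last_s != 0 && s != last_s) {
          a <- min(j, last_j)
          b <- max(j, last_j)
          return(wavelengths[a] + d2[a] / (d2[a] - d2[b]) *
                   (wavelengths[b] - wavelengths[a]))
        }
        last_s <- s
        last_j <- j
      }
      j <- j + step
    }
    NA_real_
  }
  left <- scan(-1L, i_lo)
  right <- scan(1L, i_hi)
  list(lambda_left = if (is.na(left)) wavelengths[i_lo] else
         max(left, wavelengths[i_lo]),
       lambda_right = if (is.na(right)) wavelengths[i_hi] else
         min(right, wavelengths[i_hi]),
       clamped_left = is.na(left), clamped_right = is.na(right))
}

# All five operators for one spectrum and one range.
extract_range_features <- function(intensities, lo, hi,
                                   wavelengths = ANALYSIS_GRID,
                                   sg_window = 11L, sg_order = 2L,
                                   d2 = NULL) {
  ch <- chord_slope(intensities, lo, hi, wavelengths)
  de <- chord_deficit(intensities, ch, wavelengths)
  fl <- inflection_points(intensities, lo, hi, de$lambda_max_diff,
                          wavelengths, sg_window, sg_order, d2 = d2)
  c(slope = ch$slope, max_diff = de$max_diff,
    lambda_max_diff = de$lambda_max_diff,
    infl_left = fl$lambda_left, infl_right = fl$lambda_right)
}

.feature_operators <- c("slope", "max_diff", "lambda_max_diff",
                        "infl_left", "infl_right")

#' Names of the full feature vector, in deterministic order
#'
#' Fiber-major, then range, then operator: `f<fiber>.<range>.<operator>`.
#'
#' @param ranges Range set (see [default_feature_ranges()]).
#' @param n_fibers Number of fibers.
#' @return Character vector of length `n_fibers * nrow(ranges) * 5`.
#' @export
feature_names <- function(ranges = default_feature_ranges(), n_fibers = 5L) {
  as.vector(vapply(seq_len(n_fibers), function(f) {
    as.vector(vapply(seq_len(nrow(ranges)), function(r) {
      paste0("f", f, ".", ranges$name[r], ".", .feature_operators)
    }, character(5L)))
  }, character(nrow(ranges) * 5L)))
}

#' Extract the full feature vector for one location
#'
#' @param spectra 5 x 1200 matrix of normalized analysis spectra (one fiber
#'   per row).
#' @param ranges Wavelength-range set (default: [default_feature_ranges()]).
#' @param sg_window,sg_order Savitzky-Golay parameters for inflection
#'   detection.
#' @return Named numeric vector with `5 * nrow(ranges) * 5` entries (400 for
#'   the default 16 ranges).
#' @export
extract_features <- function(spectra, ranges = default_feature_ranges(),
                             sg_window = 11L, sg_order = 2L) {
  if (!is.matrix(spectra) || nrow(spectra) != 5L) {
    abort_input("expected a 5 x %d spectra matrix (one row per fiber)",
                length(ANALYSIS_GRID))
  }
  if (ncol(spectra) != length(ANALYSIS_GRID)) {
    abort_input("spectra must be on the 1200-sample analysis grid")
  }
  out <- numeric(0)
  for (f in 1:5) {
    x <- spectra[f, ]
    d2 <- sg_second_derivative(x, sg_window, sg_order)
    for (r in seq_len(nrow(ranges))) {
      out <- c(out, extract_range_features(x, ranges$lo[r], ranges$hi[r],
                                           sg_window = sg_window,
                                           sg_order = sg_order, d2 = d2))
    }
  }
  names(out) <- feature_names(ranges)
  out
}

#' Build the cohort feature table
#'
#' MSC-normalizes the preprocessed spectra against the supplied reference
#' and extracts the full feature vector for every location.
#'
#' @param prep Output of [preprocess_cohort()].
#' @param reference An [fit_msc_reference()] object (training-fold mean).
#' @param truth Ground-truth data.frame (provides `label` per location).
#' @param ranges,sg_window,sg_order Feature-extraction configuration.
#' @return data.frame: location_id, patient_id, context, label, then one
#'   column per feature.
#' @export
cohort_feature_table <- function(prep, reference, truth,
                                 ranges = default_feature_ranges(),
                                 sg_window = 11L, sg_order = 2L) {
  norm <- msc_normalize(prep$spectra, reference)
  loc_ids <- unique(prep$index$location_id)
  fmat <- matrix(NA_real_, nrow = length(loc_ids),
                 ncol = 5L * nrow(ranges) * 5L)
  for (i in seq_along(loc_ids)) {
    rows <- prep$index$row[prep$index$location_id == loc_ids[i]]
    fmat[i, ] <- extract_features(norm[rows, , drop = FALSE], ranges,
                                  sg_window, sg_order)
  }
  colnames(fmat) <- feature_names(ranges)
  meta_idx <- match(loc_ids, prep$index$location_id)
  meta <- data.frame(
    location_id = loc_ids,
    patient_id = prep$index$patient_id[meta_idx],
    context = prep$index$context[meta_idx],
    label = truth$label[match(loc_ids, truth$location_id)],
    stringsAsFactors = FALSE)
  cbind(meta, as.data.frame(fmat))
}
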