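# Gaussian-band chromophore absorption templates for the forward model.
#
# Breast tissue optics in the 400-1600 nm window is dominated by fat, water
# and collagen absorption in the NIR and by hemoglobin in the visible range.
# The simulator does not reproduce published extinction tables; it places
# Gaussian bands at the canonical band centers (fat ~930/1210 nm, water
# ~970/1190/1450 nm, collagen ~1030/1500 nm, oxy-/deoxy-hemoglobin visible
# bands) so that class-structured spectra show realistic feature behavior.

#' Construct a chromophore absorption template
#'
#' A template is a baseline plus a sum of Gaussian absorption bands,
#' `mu_a(lambda) = baseline + sum_b amplitude_b * exp(-(lambda - center_b)^2 /
#' (2 * width_b^2))`.
#'
#' @param name Identifier, e.g. `"fat"`.
#' @param centers,widths,amplitudes Numeric vectors of equal length: band
#'   center (nm, within 200-1750), Gaussian width sigma (nm, > 0) and peak
#'   amplitude (absorption units, >= 0). May be empty.
#' @param baseline Constant absorption offset (>= 0).
#' @return An object of class `chromophore_template`.
#' @export
chromophore_template <- function(name, centers = numeric(), widths = numeric(),
                                 amplitudes = numeric(), baseline = 0) {
  stopifnot(length(centers) == length(widths),
            length(centers) == length(amplitudes))
  if (any(amplitudes < 0)) abort_input("band amplitudes must be >= 0")
  if (any(widths <= 0)) abort_input("band widths must be > 0")
  if (length(centers) && (any(centers < 200) || any(centers > 1750))) {
    abort_input("band centers must lie within 200-1750 nm")
  }
  if (baseline < 0) abort_input("baseline must be >= 0")
  structure(
    list(name = name, centers = as.numeric(centers),
         widths = as.numeric(widths), amplitudes = as.numeric(amplitudes),
         baseline = as.numeric(baseline)),
    class = "chromophore_template"
  )
}

#' Evaluate a chromophore template on a wavelength grid
#'
#' @param template A [chromophore_template()].
#' @param wavelengths Ascending numeric vector of wavelengths (nm).
#' @return Numeric vector of absorption values (finite, >= 0).
#' @export
evaluate_absorption <- function(template, wavelengths) {
  stopifnot(inherits(template, "chromophore_template"))
  if (length(wavelengths) == 0L) abort_input("empty wavelength vector")
  if (is.unsorted(wavelengths)) abort_input("wavelengths must be ascending")
  mu <- rep(template$baseline, length(wavelengths))
  for (b in seq_along(template$centers)) {
    mu <- mu + template$amplitudes[b] *
      exp(-(wavelengths - template$centers[b])^2 / (2 * template$widths[b]^2))
  }
  mu
}

#' Default absorber set of the spectra simulator
#'
#' Fat, water, collagen and oxy-/deoxy-hemoglobin as Gaussian-band templates.
#' Amplitudes are in arbitrary absorption units chosen so that typical tissue
#' compositions produce reflectance dips of realistic relative depth near the
#' fat (1210 nm) and water (1450 nm) bands; only band locations and ordering
#' matter for the downstream features.
#'
#' @return Named list of `chromophore_template` objects.
#' @export
default_chromophores <- function() {
  list(
    fat = chromophore_template(
      "fat",
      centers = c(930, 1210), widths = c(18, 28), amplitudes = c(0.55, 1.6),
      baseline = 0.05),
    water = chromophore_template(
      "water",
      centers = c(970, 1190, 1450), widths = c(28, 40, 45),
      amplitudes = c(0.45, 0.55, 2.4), baseline = 0.02),
    collagen = chromophore_template(
      "collagen",
      centers = c(1030, 1500), widths = c(35, 55), amplitudes = c(0.55, 0.9),
      baseline = 0.03),
    oxy_hemoglobin = chromophore_template(
      "oxy_hemoglobin",
      centers = c(540, 577), widths = c(16, 12), amplitudes = c(3.2, 3.0),
      baseline = 0.01),
    deoxy_hemoglobin = chromophore_template(
      "deoxy_hemoglobin",
      centers = c(555, 760), widths = c(20, 22), amplitudes = c(3.4, 0.65),
      baseline = 0.01)
  )
}
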