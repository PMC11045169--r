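---
title: "Classifying breast resection margins from diffuse reflectance spectra"
author: "drsmargin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying breast resection margins from diffuse reflectance spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drsmargin)
```

## The problem

In breast-conserving surgery the excised specimen's margins must be free of
tumor; a positive margin (tumor within 2 mm of the inked resection surface)
often means re-excision. Diffuse reflectance spectroscopy (DRS) probes the
margin optically: broadband light is delivered through illumination fibers
and the diffusely reflected spectrum carries the absorption signatures of
the tissue within a few millimeters of the probe. Tumorous breast tissue is
water- and collagen-rich and fat-poor; healthy breast tissue is dominated by
fat. Those compositional differences shape the near-infrared spectrum —
most visibly around the fat band near 1210 nm and the water band near
1450 nm — and a classifier trained on spectral features can flag suspicious
margin locations in seconds.

`drsmargin` implements that analysis end to end: preprocessing of raw
dual-spectrometer, five-fiber measurements; extraction of chord-based
spectral features; minimum-redundancy maximum-relevance (MRMR) feature
selection; four classifier types under patient-grouped repeated
cross-validation with configurable training regimes (ex vivo, in vivo, or
both — tested always on in vivo locations); and evaluation with the
Matthews correlation coefficient (MCC), ROC analysis, operating points and
a tumor-percentage versus margin-distance misclassification analysis.
Because clinical margin spectra are not publicly distributable, the package
also contains a synthetic cohort simulator and a synthetic histology
renderer, so the entire pipeline is exercised and tested on generated data
with the statistical structure the analysis assumes.

## Measurement model and preprocessing

A raw measurement of one margin location consists of five fibers, each
recording three consecutive replicates on two spectrometer ranges: visible
(200–1160 nm) and near-infrared (900–1750 nm). Preprocessing is fixed in
this order:

1. **Replicate averaging** — pointwise mean of the three replicates.
2. **Stitching** — both ranges are resampled to a uniform 1 nm grid by
   linear interpolation and blended in the 900–1160 nm overlap with a
   linear crossfade (visible weight 1 at 900 nm, 0 at 1160 nm). The
   crossfade avoids a step at the hand-over; `vis_priority` /
   `nir_priority` switches are available for sensitivity checks.
3. **Trimming** — the noisy extremities (below 400 nm and at or above
   1600 nm) are removed. The analysis grid is the half-open window
   [400, 1600) nm sampled every 1 nm: samples at 400, 401, …, 1599 nm,
   i.e. exactly 1200 wavelengths. The half-open convention is what makes
   the 1200-sample count exact on a 1 nm grid.
4. **Multiplicative scatter correction (MSC)** — each spectrum `x` is
   regressed on a reference spectrum `m` (ordinary least squares over all
   1200 wavelengths, `x ≈ a + b·m`) and replaced by `(x − a)/b`. This
   inverts additive offsets and multiplicative path-length distortions
   exactly and is idempotent. The reference is the pointwise mean of the
   *training* spectra only: under cross-validation a full-dataset mean
   would leak test information into the normalization, so the fitted
   reference travels with the model artifact and is applied unchanged to
   test spectra. Slopes with `|b| < 1e-8` are rejected as degenerate
   (a constant spectrum carries no scatter information and would divide
   by ~0).

## Spectral features

For each of 16 configurable wavelength ranges (defaults bracket the NIR
fat, water and collagen dips: 1213–1248, 931–1195, 1224–1331, 1142–1225,
1021–1102, 999–1034, 1395–1430, 1404–1437, 1467–1502, 1121–1401, 932–967,
1112–1147, 1201–1236, 1382–1574, 883–1149 and 926–1149 nm), five operators
are evaluated per fiber:

* **chord slope** — the line through the intensity maxima of the first and
  last quarter of the range (quarters by wavelength span; argmax ties take
  the smaller wavelength); its gradient in intensity/nm;
* **chord deficit** — the maximum of `chord − spectrum` between the chord
  endpoints (an absorption dip sits *below* its chord, so the deficit is
  the dip depth relative to the local baseline), and
* **its wavelength** (first occurrence on ties, ascending scan);
* **left and right inflection points** — the second derivative of the
  Savitzky–Golay-smoothed spectrum (window 11 samples, polynomial order 2,
  both configurable) is scanned outward from the deficit wavelength; the
  nearest sign change on each side, located by linear interpolation of the
  zero crossing, is the inflection wavelength. Curvature below `1e-8`
  of the spectrum's intensity scale is treated as zero so straight
  segments do not produce spurious crossings from floating-point noise;
  if no crossing occurs before the range edge, the edge is returned and
  flagged as clamped.

Five fibers × 16 ranges × 5 operators = 400 features per location (80 per
fiber). The features are translation invariant and scale equivariant:
adding a constant changes nothing, multiplying by `k > 0` scales slope and
deficit by `k` and leaves all wavelength-valued features unchanged. The
cross-validation driver exploits this algebra: raw features are extracted
once, and each fold's MSC (an affine map per spectrum) is applied by
rescaling the amplitude-valued features by the fitted `1/b` — exactly
equivalent to normalizing first (a unit test holds the two paths equal to
1e-9), at a fraction of the cost.

## Feature selection

MRMR ranks features greedily: the first pick maximizes relevance
`MI(f; y)`; each later pick maximizes `MI(f; y) − mean_{s∈S} MI(f; s)`
(the MID, difference, scheme; the quotient scheme is a config switch).
Mutual information is the plug-in estimate in bits (log base 2, which
makes the balanced identical-variable case exactly 1 bit), after
equal-frequency discretization into 10 bins (tied quantiles merged).
Features with an importance score ≥ 0.015 at selection time are kept —
an inclusive cut. Selection runs inside each training fold only; the
selected set is part of the fold's model state. Because the greedy step is
O(p) MI evaluations against every already-selected feature, the CV driver
caps the ranking depth at 60 features per fold (the threshold is applied
within that sequence); the standalone `mrmr_rank()` ranks all features,
and the oracle tests compare that full ranking against a brute-force
reimplementation. Per-fold selections differ; the reported "optimum
feature" list is the modal selection across folds (`modal_selection()`):
features chosen in at least half the folds, ordered by frequency and mean
rank — the aggregation rule is explicit because a single list must be
reported from many folds.

## Classifiers and cross-validation

Four model types share one interface (continuous malignancy score in
[0, 1]):

* linear SVM and quadratic SVM (`e1071`, polynomial degree 2, box
  constraint 1 on standardized features, Platt-style probability
  calibration for comparable scores);
* weighted KNN, k = 10 with inverse-squared-distance weights;
* **RUSBoost**, implemented in the package: AdaBoost over depth-5 `rpart`
  trees where, before each round, the majority class is randomly
  undersampled without replacement — sampling probabilities proportional
  to the current boosting weights — down to a 50:50 ratio. The round's
  tree is fitted with the boosting weights, its weighted error `e_t` is
  computed on the *full* training set, rounds with `e_t ≥ 0.5` are
  discarded and resampled (up to 10 retries, then the ensemble stops
  growing), and weights update with `α_t = 0.1 · ln((1 − e_t)/e_t)`
  (learning rate 0.1, 100 rounds by default). The ensemble score is the
  α-weighted mean of the trees' malignant-class probabilities; an
  ensemble that accepted no round scores 0.5 everywhere, which is also
  what uninformative input converges to. Undersampling is the standard
  counter to the strong class imbalance of margin cohorts (most probed
  locations are healthy).

Cross-validation is 5-fold with 20 iterations by default, partitioned at
the *patient* level: all locations of a patient share a fold, because
locations within a patient are correlated (the simulator encodes this as a
shared multiplicative composition effect) and location-level splits would
leak. Each shuffled patient is assigned to the currently smallest fold,
malignant-bearing patients first, so folds are size-balanced and every
fold receives malignant patients when feasible. The test set of a fold is
always its patients' *in vivo* locations; the training set is the
remaining patients' locations filtered by the regime (`ex_vivo_only`,
`in_vivo_only`, `both`). Patient exclusivity is asserted on every fold at
run time.

## Evaluation

* **MCC** from the confusion counts, `(tp·tn − fp·fn)/√((tp+fp)(tp+fn)(tn+fp)(tn+fn))`,
  with the standard convention MCC = 0 when any denominator factor is zero
  (the formula is undefined there). Reported per iteration at that
  iteration's MCC-maximizing threshold, then averaged (mean, sample SD,
  percentile 95% CI over the 20 iteration-level values — the iteration
  structure is the only resampling the design provides; a location
  bootstrap would be the alternative).
* **ROC/AUC** by threshold sweep with tied scores grouped and trapezoidal
  area; per-iteration AUC and the pooled-scores curve are both reported.
* **Two operating points**, both reported because both are legitimate:
  the minimum-expected-cost point (`cost_fp·fpr·(1−π) + cost_fn·(1−tpr)·π`,
  default unit costs and empirical prevalence π, ties toward higher
  sensitivity) supplies the headline sensitivity/specificity; the
  MCC-maximizing threshold drives the per-iteration MCC and the
  misclassification scatter.
* **Misclassification scatter** — for every malignant in vivo location:
  mean tumor-margin distance, tumor area percentage, and whether it was
  classified correctly, plus the Pearson correlation between percentage
  and distance. The simulator builds in the negative relation (see below),
  so a correctly recovered cohort shows r < 0, with misclassified tumor
  locations concentrated at large distance / low percentage.

## The synthetic cohort

The simulator generates the study conditions the analysis assumes, not
radiometrically accurate spectra:

* **Forward model** — modified Beer–Lambert,
  `R(λ) = g · exp(−ℓ · Σᵢ fᵢ · μa,ᵢ(λ))`, with a wavelength-independent
  effective path length per measurement (log-normal, SD 0.05). Full
  diffusion theory or photon transport is deliberately out of scope: the
  downstream pipeline needs class-structured spectra with the right band
  geometry, nothing more.
* **Chromophores** — Gaussian-band absorption templates at canonical band
  centers: fat 930/1210 nm, water 970/1190/1450 nm, collagen 1030/1500 nm,
  oxy-/deoxy-hemoglobin visible bands. Published extinction tables are not
  reproduced; only band locations and relative depths matter for the chord
  features.
* **Composition priors** — Dirichlet draws (concentration 60) around class
  means: healthy (fat 0.60, water 0.22, collagen 0.14, blood 0.04), tumor
  (fat 0.18, water 0.46, collagen 0.31, blood 0.05). These are stand-ins
  chosen to be physiologically plausible, *not* estimates of any clinical
  cohort. `class_separation` interpolates the two means toward their
  midpoint; it is the dial used to verify that easier problems give higher
  cross-validated AUC. Its default, 0.6, was calibrated once so that
  default-condition cross-validated MCCs land in the 0.6–0.8 range typical
  of margin cohorts instead of being trivially separable;
  `class_separation = 1` is the well-separated setting used by the
  pipeline-recovery checks. Oxygen saturation is drawn high in vivo
  (0.80–0.97) and low ex vivo (0.25–0.60), reflecting perfusion loss after
  excision.
* **Patient random effect** — a multiplicative log-normal perturbation
  (SD 0.08) of the composition shared by all locations of a patient; this
  is the correlation structure that justifies patient-level CV splits.
* **Noise** — per-replicate gain jitter (log-normal SD 0.02), additive
  Gaussian noise (SD 0.002) inflated tenfold inside 350–400 nm and
  1600–1700 nm to emulate the noisy spectral extremities that motivate the
  trim; per-fiber composition jitter (SD 0.03).
* **Ground truth** — each location is malignant with the configured rate
  (default 0.10). Malignant locations draw central/min/max tumor-margin
  distances within the 2-mm band and set
  `tumor_pct = clip(100·(1 − d_mean/2 mm) + ε, 1, 100)` with Gaussian ε
  (SD 8 percentage points) — one parameter that reproduces the negative
  distance–percentage relation. The location's composition mixes the tumor
  and healthy priors with weight `0.4 + 0.6·tumor_pct/100`, so deep-margin,
  low-percentage tumors are genuinely harder — the mechanism behind the
  misclassification scatter. All randomness flows from one seed through
  named substreams (`derive_seed`), so identical configs are bit-identical
  and changing one stage's draws cannot perturb another's.

What the simulator does **not** emulate: instrument spectral response,
spectralon calibration, probe pressure and contact effects, DCIS vs
invasive subtypes, and the long-tailed composition heterogeneity of real
cohorts. Tests passing on simulated cohorts therefore demonstrate that the
pipeline recovers structure it is designed for; they are not evidence of
clinical performance.

## Synthetic histology and the 2-mm band

`render_section()` draws an inked margin (horizontal ink line, tissue
below) whose tumor upper edge follows the truth's min/central/max
distances and whose thickness is solved so the in-band tumor area matches
`tumor_pct`; when distance noise makes the recorded percentage
geometrically unreachable at the recorded distances, the edge is scaled
toward the ink — the area percentage and label, not the distances, are the
round-trip invariant. The RGB palette gives fat the brightest green
channel and tumor the darkest, with the default fat/connective threshold
at green 200/255 calibrated once against that palette.

`band_region()` selects pixels within 2 mm of the ink polyline on the
tissue side (the side holding the majority of non-background pixels);
`tissue_percentages()` takes tumor from the annotation mask and splits the
healthy remainder by the green threshold; `margin_distances()` samples the
polyline at one-pixel arc spacing and takes each sample's distance to the
nearest in-band tumor pixel (capped at the band depth) — minimum and
maximum over samples, the central value at the arc-length midpoint, and
their average. Percentages are 2-D area fractions of the section; no
volumetric correction is attempted even though the probed volume is 3-D.

## Problem sizes used by the tests and acceptance script

The package's own verification runs use: unit fixtures of 12–30 patients;
the end-to-end recovery run at 100 patients × 6 locations, 10% malignant,
RUSBoost, regime `both`, 5-fold CV with 5 iterations; and the
model-ordering comparison at 40 patients × 6 locations with 2 iterations
across 5 seeds. These sizes were chosen once as the smallest cohorts at
which the binomial noise on iteration-level MCC/AUC is small relative to
the margins being asserted.

## Interface choices

The pipeline is driven from R: `simulate_cohort()`, `run_cross_validation()`,
`evaluate_cv()` and the one-call `run_experiment()` (which writes the
resolved YAML config, score tables, per-fold selections, ROC points, the
report as CSV/JSON, and a structured log with seed and config hash into a
run directory). A standalone shell CLI would add a packaging layer without
adding capability for an R audience, so the shell entry point is the
reproduction script `scripts/acceptance.R`; all I/O goes through exported,
schema-validated functions (`write_spectra_csv()`/`read_spectra_csv()`,
`write_truth_csv()`/`read_truth_csv()`, `write_section()`).

## Known limitations

* The 16-range feature set is a reconstruction anchored to the ranges that
  appear in published feature lists for this probe family; the original
  80-feature definition lives in prior work and is configurable here
  rather than hard-coded.
* MSC could equally be referenced to the mean of the whole dataset rather
  than the training fold; the full-dataset variant leaks test information
  under cross-validation and is intentionally not offered.
* Platt calibration inside `e1071` uses internal folds; scores are
  comparable across models but are not calibrated probabilities in the
  strict sense.
* On simulated cohorts RUSBoost does **not** consistently out-rank the
  linear SVM: after MSC and chord features the simulator's two classes are
  close to linearly separable with roughly elliptical noise — the regime
  where a maximum-margin linear classifier is near-optimal and
  undersampling mostly discards information. RUSBoost's advantage on
  clinical margin data comes from heterogeneity and nonlinearity that the
  semi-empirical forward model deliberately does not reproduce; comparisons
  between model types on simulated cohorts should be read with that in
  mind.
* The plug-in MI estimator is biased upward at small n (≈ (kx−1)(ky−1) /
  (2n·ln2) bits); with n in the hundreds and 10×2 bins the bias is well
  below the 0.015 selection threshold, but rankings at very small n should
  be treated with care.
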