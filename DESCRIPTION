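Package: drsmargin
Title: Diffuse Reflectance Spectroscopy Pipeline for Breast Margin Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible analysis pipeline for classifying
    breast resection-margin tissue from dual-spectrometer, five-fiber diffuse
    reflectance spectra. Covers replicate averaging, range stitching,
    extremity trimming and multiplicative scatter correction; chord-based
    spectral feature extraction (slope, chord deficit, inflection points)
    over configurable near-infrared wavelength ranges; minimum-redundancy
    maximum-relevance (MRMR) feature selection; imbalance-aware
    classification (linear and quadratic SVM, distance-weighted KNN, and an
    in-package RUSBoost) under patient-grouped repeated cross-validation;
    and evaluation via the Matthews correlation coefficient, ROC analysis,
    cost-optimal operating points and tumor-percentage versus margin-distance
    misclassification analysis. Because clinical spectra are not publicly
    available, the package ships a synthetic tissue-spectra simulator (a
    Gaussian-band chromophore, modified Beer-Lambert forward model) and a
    synthetic histology renderer with a 2-mm-band ground-truth quantifier, so
    the entire pipeline is exercised on generated data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    signal,
    rpart,
    e1071,
    jsonlite,
    yaml,
    rlang,
    png
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
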