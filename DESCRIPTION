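Package: pepclass
Title: Serum Peptidome Profiling and Chemotherapy-Response Classification
    from MALDI-TOF Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An open re-implementation of the serum MALDI-TOF peptidome
    workflow used to predict first-line chemotherapy response in small-cell
    lung cancer: total-ion-current normalization, common-peak recalibration,
    morphological top-hat baseline subtraction, Savitzky-Golay smoothing,
    signal-to-noise thresholded peak detection with zero-level area
    integration, cross-spectrum peak alignment, Welch-t / ROC-AUC
    differential-peak screening, genetic-algorithm feature selection wrapping
    a k-nearest-neighbor classifier with repeated stratified-holdout
    cross-validation, blinded classification with confusion-matrix reporting,
    and Kaplan-Meier / log-rank survival analysis of classifier-assigned
    groups. A seeded synthetic-cohort generator parameterized by published
    group summary statistics stands in for undeposited patient sera, so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
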