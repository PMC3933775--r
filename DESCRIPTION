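Package: topodecode
Title: Single-Trial EEG Decoding of Auditory Categories from Voltage
    Topographies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decoding of auditory stimulus categories from single-trial EEG
    voltage topographies. Models the instantaneous scalp topographies of each
    condition with a Gaussian mixture, estimates the time periods at which the
    condition-specific template maps differ most, classifies held-out trials
    by summed log-likelihood ratios along those periods, and assesses
    significance with label-permutation null models, a signed-rank decision
    and a group-level binomial test. Includes the topographic consistency
    test (global field power against an electrode-shuffling null with FDR
    correction), stimulus acoustic-control statistics (bootstrap bin-wise
    spectrogram tests with spatial thresholding, harmonics-to-noise ratio),
    preprocessing (band-pass/notch filtering, epoching, amplitude-based
    artifact rejection, cross-validation/validation splits), and a synthetic
    session generator with known ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    mclust,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
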