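Package: drowseeg
Title: Single-Channel EEG Drowsiness Detection with Person-Adaptive Spectral Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects drowsiness (wake versus stage-1 sleep) from a single
    EEG channel using person-adaptive spectral features anchored on the
    Individual Alpha Frequency (IAF). Raw signals are band-pass filtered,
    segmented into 30 s epochs, and transformed to Hanning-windowed FFT
    power spectral densities; five features per epoch (power at the IAF,
    at the theta frequency IAF - 4 Hz, at 3 Hz and 4 Hz, and the
    slow-to-alpha band power ratio) feed a small per-subject multilayer
    perceptron whose hidden-layer size is swept over 5 to 25 neurons.
    Performance is estimated by stratified 10-fold cross-validation with
    sensitivity, specificity and accuracy reporting. A seeded synthetic
    EEG cohort generator with per-subject alpha peaks over 1/f background
    noise makes the whole pipeline testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    nnet,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
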