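Package: emgsleep
Title: Sleep/Wake Scoring from Anterior Tibialis Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Epoch-by-epoch sleep/wake estimation from overnight anterior
    tibialis surface electromyography alone, without EEG. Implements a
    time-domain estimator (per-second signal energy against an adaptive
    amplitude threshold, with high-EMG-second counting) and a
    frequency-domain estimator (band-masked per-epoch spectral total power
    against a mean-plus-SD threshold), leave-one-out cross-validated grid
    calibration of the threshold-selection factors, the full set of
    epoch-by-epoch agreement statistics (sensitivity, specificity, PPV,
    NPV, accuracy, Cohen's kappa, F-measure), sleep-efficiency comparison,
    posture-stratified agreement, and a synthetic overnight-EMG generator
    with ground-truth hypnograms (normal, OSA-like and PLMD-like profiles)
    so the whole pipeline is testable without clinical recordings. Reads
    and writes EDF and plain-text signal, hypnogram and posture formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
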