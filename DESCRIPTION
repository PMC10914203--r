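Package: ppgarousal
Title: Photoplethysmogram Frequency and Amplitude Responses to Arousals from Sleep
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies photoplethysmogram (PPG) responses to
    arousals from sleep and compares them across arousal causes. Implements
    the power-weighted mean instantaneous frequency and sliding-window
    instantaneous amplitude characteristics of the PPG, a multistart bounded
    least-squares fit of a triple-logistic step model to each arousal segment
    with categorization into response, delay and recovery calls, arousal
    inclusion and cause-classification rules for polysomnography annotations
    (spontaneous versus obstructive apnea/hypopnea, with or without oxygen
    desaturation), stable-sleep baseline sampling, and subject-paired
    resampled Wilcoxon inference with relative risks. A synthetic
    polysomnography cohort generator with known ground truth makes every
    stage testable without clinical recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    signal,
    zoo,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
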