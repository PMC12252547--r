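Package: striatlearn
Title: Behavioral-Strategy and Striatal Spike-Train Analysis of Auditory
    Discrimination Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy analysis pipeline for two-alternative auditory
    discrimination learning with chronic striatal recordings. Computes
    per-session behavioral metrics (success, omission, bias, response time),
    trial-by-trial win-shift-win / lose-shift-lose strategy scores, a
    four-parameter logistic learning-curve fit with early/middle/late stage
    assignment, cluster-quality filtering and putative cell-type
    classification (MSN/FSI/TAN/UI) from waveform width, long-ISI
    proportion and autocorrelogram post-spike suppression, peri-event
    response detection with rank tests and 50-ms PSTHs, bin-by-bin auROC
    coding profiles, and matched-trial resampled neuron-proportion
    comparisons across learning stages. Includes a seeded synthetic-data
    generator (task behavior plus inhomogeneous-Poisson spike trains) so
    every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
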