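Package: gridtap
Title: Simulation and Offline Analysis of a Tactile P300 Brain-Computer
    Interface Recorded with Scalp and Around-the-Ear EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate and analyse a four-position vibrotactile P300
    oddball brain-computer interface recorded simultaneously with a
    12-channel scalp EEG and the 20-electrode around-the-ear cEEGrid.
    Provides the oddball session scheduler, a calibrated synthetic EEG
    generator with event-related potential templates and artifact epochs,
    the offline signal path (zero-phase band-pass filtering, epoching,
    baseline correction, amplitude-threshold artifact rejection, class
    averaging), ERP window-mean and peak-latency feature extraction,
    stepwise linear discriminant analysis (SWLDA) classification with
    block-wise leave-one-out cross-validation and exact binomial
    chance-level bounds, an adaptive two-stimulus intensity-discrimination
    task with sigmoidal psychometric threshold fitting, and group-level
    statistics (paired t, Pearson correlation, repeated-measures ANOVA with
    Greenhouse-Geisser correction and Bonferroni post-hocs) with report
    tables and plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
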