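Package: avbisect
Title: Audio-Visual Bisection Simulation and Maximum-Likelihood Cue-Combination Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates observers performing audio-visual temporal and spatial
    bisection tasks under sensory conflict, with QUEST-style adaptive stimulus
    placement, and analyses the resulting trial data with the standard
    psychophysical toolchain: maximum-likelihood cumulative-Gaussian fits with
    bootstrap standard errors, bias-corrected points of subjective equality,
    pooled bimodal thresholds, maximum-likelihood-estimation (MLE) integration
    predictions for bimodal thresholds and PSEs, conflict-slope cue weights, an
    explained-variance statistic, and group-level one-tailed threshold tests.
    Includes an end-to-end pipeline for synthetic developmental cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
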