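Package: brainclocks
Title: Brain Clocks, Creative Experience, and Whole-Brain Model Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline linking functional-connectivity brain clocks
    to creative experience. Generates synthetic age- and expertise-structured
    cohorts of region-by-region connectivity matrices from a Stuart-Landau
    (Hopf) whole-brain model, trains linear support-vector-regression brain
    clocks with cross-validated brain-age-gap estimation and age-bias
    correction, computes global and local graph efficiency over proportional
    thresholds, fits the model's global coupling by a structural-similarity
    sweep against the linearized (Lyapunov) connectivity prediction, and
    tests brain-map associations with variogram-matched spatial surrogates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    igraph,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
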