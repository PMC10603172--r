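Package: dyadsim
Title: Coupled Two-Agent Simulation of Task-Constrained Interpersonal
    Coordination
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Discrete-time, noise-driven simulation of two interacting
    agents whose self- and cross-influences are encoded by a 2x2 ternary
    "context matrix" of task constraints (active, inactive, inhibitory),
    together with an analysis pipeline for interpersonal synchrony and
    complementarity: exhaustive context sweeps recording per-run Pearson
    correlations, threshold classification, inhibitory-parameter
    prevalence with chi-square tests, dummy-coded regression models
    compared by R-squared/AIC/BIC, lagged cross-correlation functions,
    and turn-taking lag histograms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
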