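Package: casecrossnc
Title: Time-Stratified Case-Crossover Analysis with Negative-Control
    Bias Correction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for time-stratified case-crossover analysis of
    short-term environmental exposures and mortality: bidirectional
    referent-day selection, distributed-lag and moving-average exposure
    features, conditional logistic regression implemented from the
    likelihood up, and a double negative-control causal layer (lead-1
    negative exposure control, negative outcome control, coefficient-
    difference bias correction, and a two-stage surrogate-confounder
    estimator). Includes a synthetic-data generator that plants known
    effect sizes and a known unmeasured time-varying confounder so the
    whole pipeline is testable by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
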