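Package: mdchange
Title: Longitudinal Change, Reliability and Stability of Mammographic Density Measures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing longitudinal mammographic density readings in
    tamoxifen prevention cohorts: construction of matched analysis samples,
    variance-stabilising transformations with baseline inter-quartile-range
    standardisation, a linear mixed model with a year-1 step and post-year-1
    ramp in the treated group, model-based reliability (intraclass correlation
    with cluster-bootstrap confidence intervals), control-calibrated cutpoints
    for classifying density decrease, and a prequential stability test that
    compares individual against cohort-mean 1-year change as predictors of
    2-year change. Includes a synthetic-cohort generator reproducing the
    statistical structure of such studies so the full pipeline is testable
    without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    lme4,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
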