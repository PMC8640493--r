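Package: brgpi
Title: Rank-Based Gene-Pair Signatures for Immunotherapy Benefit Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and evaluation of normalization-free gene-pair signatures
    for progression-free survival under immune-checkpoint blockade. Candidate
    features are within-sample relative-expression indicators (gene A greater
    than gene B), screened by univariate Cox regression, combined by forward
    stepwise multivariate Cox selection into a coefficient-weighted index, and
    dichotomized at a cutoff chosen on an inverse-probability-of-censoring
    weighted time-dependent ROC curve at a fixed horizon. Includes the frozen
    published four-pair index for anti-PD-1-treated non-small cell lung cancer,
    a synthetic multi-platform cohort generator with planted signatures for
    end-to-end testing, Kaplan-Meier / log-rank / response-group evaluation
    reports, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    graphics,
    jsonlite,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
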