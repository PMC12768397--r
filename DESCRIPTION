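Package: wonemetrics
Title: Psychometric Validation Pipeline for a Hierarchical Stress-Resilience Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the complete psychometric computation chain used to
    develop and validate a multidimensional stress-resilience index: synthetic
    Likert item-response generation from a hierarchical (second-order) factor
    model, exploratory factor analysis (principal axis factoring with Promax
    rotation, KMO and Bartlett diagnostics, rule-based item retention),
    maximum-likelihood confirmatory factor analysis for first- and second-order
    models with fit indices and modification-index guided refinement,
    reliability and validity statistics (composite reliability, average
    variance extracted, Cronbach alpha, McDonald omega, intraclass
    correlations, HTMT ratios, hierarchical incremental validity), multigroup
    measurement-invariance testing, and a hybrid empirical-theoretical
    weighting scheme with floor renormalization for index scoring.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
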