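Package: brainpad
Title: Brain-Age Prediction and Random-Effects Meta-Analysis for
    Multi-Cohort Neuroimaging Consortia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sex-stratified ridge-regression brain-age models on
    FreeSurfer-derived regional morphometry, brain-predicted age
    difference (brain-PAD) computation, per-cohort covariate-adjusted
    linear models for diagnosis and clinical characteristics, and a
    restricted-maximum-likelihood random/mixed-effects meta-analysis
    engine with heterogeneity statistics, moderator meta-regression and
    Benjamini-Hochberg false-discovery-rate control. Includes a synthetic
    multi-cohort consortium generator emulating case-control structural
    MRI studies so the full pipeline is testable without clinical data,
    plus structure-coefficient analysis of feature importance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    MASS
Config/testthat/edition: 3
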