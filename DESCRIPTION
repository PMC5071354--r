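Package: normforge
Title: Regression-Based Normative Databases from Multi-Study Control Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds demographically corrected, normality-transformed normative
    databases for neuropsychological (and other) test scores by combining
    healthy-control datasets donated by multiple studies. Implements the full
    construction pipeline: per-variable assembly of multi-study data, removal
    of impossible scores via extreme borders, a cell-count estimability screen
    for demographic effects, backward AIC selection of age, sex and education
    fixed effects in a multilevel model with a random study intercept, robust
    outlier removal on model residuals (3.5 MAD), a Box-Cox power-transform
    search that optimizes residual normality, refitting on the standardized
    transformed scale, and scoring of new patients against the stored norms
    (demographically corrected z-scores and percentiles). Includes a synthetic
    multi-study data generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    withr
Config/testthat/edition: 3
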