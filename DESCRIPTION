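Package: immunoval
Title: Analytical Validation Statistics for Multiplex Immunoassays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for the analytical validation of multiplex
    sandwich immunoassays, built around a three-analyte plasma biomarker panel
    (KIM-1, sTNFR-1, sTNFR-2) read out by electrochemiluminescence. Implements
    four-parameter logistic calibration with weighted back-calculation, limit
    of blank / detection / quantification determination by the classical
    approach with a four-part quantification-limit rule, mixing-design
    linearity assessment with allowable-deviation trimming, nested and
    multi-factor precision variance-component estimation (ANOVA
    method-of-moments and REML), multiplex non-specific binding and
    interference recovery statistics, and composite risk-score reproducibility
    with category concordance. A seeded hierarchical plate simulator generates
    every input from known ground truth for verification studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    lme4,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
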