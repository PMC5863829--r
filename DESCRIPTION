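Package: placmed
Title: Placental Methylation, Surface Area, and Full-Term Low Birth
    Weight Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how placental CpG methylation relates to
    full-term low birth weight through placental surface area.
    Implements EpiTYPER-style beta-value quality control,
    standardized-covariate logistic and linear association models with
    correlation-block Bonferroni correction, Kenny-style mediation
    condition checks, the Sobel test, and an imputation-based
    natural-effects estimator that decomposes the total odds ratio into
    natural direct and indirect components with bootstrap confidence
    intervals.  A synthetic cohort generator with known causal structure
    and an EpiTYPER-style plate simulator make the whole pipeline
    testable without access to study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
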