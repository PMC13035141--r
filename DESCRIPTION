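Package: deatonuv
Title: Price and Expenditure Elasticities of Demand from Household Survey Unit Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-stage estimation of the price and expenditure elasticity of
    demand for a survey-recorded good (cigarettes) from clustered household
    expenditure microdata, following Deaton's unit-value method adapted to a
    short household panel. Stage one fits fixed-effects regressions of log
    unit value and budget share on household resources and demographics;
    stage two aggregates purged residuals to survey clusters and applies an
    errors-in-variables correction before recovering the structural price
    response through Deaton's quality-correction identities. Includes a
    synthetic clustered-survey generator with known parameters for validation,
    weighted descriptive statistics, a cluster bootstrap for inference, and a
    config-driven pipeline runner with reproducible manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
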