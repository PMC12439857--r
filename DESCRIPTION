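Package: co2gap
Title: Estimating Arterial CO2 from Noninvasive Intraoperative Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating arterial partial pressure of carbon dioxide
    (PaCO2) in mechanically ventilated surgical patients from noninvasive
    intraoperative parameters. Provides a synthetic-cohort generator for
    intraoperative biosignals and arterial blood gas events, refinement of
    blood-gas timestamps via detection of arterial-pressure surges, windowed
    feature extraction with physiological interaction features, case-grouped
    nested cross-validated gradient-boosted regression against two end-tidal
    CO2 baselines, and a clinical agreement-evaluation suite (Bland-Altman
    limits of agreement, intraclass correlation, error banding, additive
    feature attributions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
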