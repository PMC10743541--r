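Package: certscore
Title: Ceramide and Phosphatidylcholine Risk Scores and Hypertension
    Association Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the quartile-point Coronary Event Risk Test scores
    (CERT1 from four ceramides, CERT2 from ceramide/phosphatidylcholine
    ratios), fits the associated prevalent-hypertension logistic models and
    new-onset-hypertension Cox models with attained age as the timescale,
    draws winsorized loess risk curves, and produces baseline-characteristics
    tables. Includes a seeded synthetic cohort generator calibrated to
    published population-survey marginals so the full pipeline is testable
    without access to restricted biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
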