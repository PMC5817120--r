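Package: psfland
Title: Community-Level Plant-Soil Feedback Models for Landscape Plant Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to analyse community-level plant-soil feedback (PSF)
    experiments and to project their consequences across a landscape.
    Generates synthetic two-phase common-garden experiment tables and
    landscape vegetation surveys with a configurable suppression structure,
    tests percent-cover differences among cultivated-soil treatments
    (arcsine square-root transform, one-way and site-blocked two-way
    ANOVA, Tukey compact letter displays), converts observed cover into
    per-time-step multiplicative growth rates, runs a discrete-time
    community growth model in which soil composition tracks plant
    relative abundance ("Pot-Level-K") together with a feedback-free null
    variant, and compares predicted native/non-native dominance across
    historical tillage boundaries with survey observations.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
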