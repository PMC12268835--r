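Package: mimicsLitter
Title: Microbially Explicit Litter Decomposition Modelling, Calibration to
    Empirical Drivers, and Climate-Change Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A seven-pool microbially explicit litter and soil organic matter
    model (a MIMICS variant with density-dependent microbial turnover),
    litterbag decomposition simulations overlaid on site steady states, a
    copiotroph-to-oligotroph grouping stage for taxonomy-labelled amplicon
    count tables, linear mixed-effects effect-size estimation for drivers of
    litter mass loss, Monte Carlo calibration of microbial parameters to
    observed mass loss and effect sizes, and anomaly-forced climate-change
    experiments. Ships synthetic-data generators so the full pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    deSolve,
    lme4,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
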