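Package: twinace
Title: Twin-Based Heritability of Longitudinal Brain-Structure Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for classical twin analyses of longitudinal
    phenotypes: simulation of twin cohorts with a known ACE variance structure
    on latent growth parameters, extraction of per-subject intercepts and
    slopes from repeated measurements, monozygotic/dizygotic within-pair
    Pearson correlations with a Fisher r-to-z comparison, maximum-likelihood
    ACE variance-component modeling with profile-likelihood confidence
    intervals, component-reporting decision rules, Sidak-type multiple-testing
    thresholds for correlated phenotypes, and aggregation of reported variance
    components across brain networks, regions, morphological dimensions, and
    hemispheres. Ships a reference table of published twin correlations and
    ACE estimates for eleven brain regions for worked-example arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
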