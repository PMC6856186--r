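Package: riceHg
Title: Rice Life-Cycle Mercury Biotransport and Dietary Methylmercury Exposure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Material-flow analysis of total mercury (THg) and methylmercury
    (MeHg) carried by rice through its life cycle: grain concentration
    modelling from literature-style measurement records (log-normal Monte
    Carlo medians, power-law imputation between mercury species, ordinary
    kriging to unmeasured countries), plant-organ partitioning to stems,
    leaves and bulk residues, country-level commodity mass balance with
    bilateral trade attribution, residue-fate partitioning and field-burning
    emissions, per-capita probable weekly intake, and dose-response health
    impacts (fetal IQ decrements and fatal heart attacks) with interquartile
    Monte Carlo uncertainty envelopes. Ships a synthetic-world generator that
    produces complete, internally consistent inputs with known ground truth,
    so the whole pipeline is testable without external data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    geosphere,
    tibble,
    dplyr,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
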