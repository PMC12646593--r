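Package: chemtriage
Title: Ionization-Aware Dosimetry, Baseline-Toxicity QSARs, and Triage of
    Chemical Screening Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for assembling diverse chemical collections for
    high-throughput toxicity testing. Computes Henderson-Hasselbalch
    species fractions for ionizable chemicals and ionization-corrected
    distribution ratios toward air, membrane lipid (liposomes), serum
    albumin, and structural proteins; applies a mass-balance model of
    chemical availability in serum-supplemented cell-based bioassays
    (freely dissolved fraction, nominal and freely dissolved baseline
    cytotoxicity concentrations); predicts and fits baseline-toxicity
    (narcosis) QSARs for several in vivo test systems and classifies
    specificity ratios; categorizes intrinsic hepatic clearance and
    plasma unbound fraction; and runs a staged triage pipeline
    (physicochemical, logistic, mechanistic-diversity filters) with
    full audit reporting. A seeded synthetic chemical generator
    reproduces the property distributions the pipeline assumes, so
    every stage runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
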