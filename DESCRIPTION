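Package: screendelay
Title: Scenario Analysis of Temporary Disruptions to Cervical Cancer Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A stylized microsimulation of human papillomavirus (HPV) induced
    cervical carcinogenesis coupled to a screening-cascade engine, built to
    quantify how temporary, pandemic-style interruptions of primary cervical
    screening affect women with heterogeneous screening histories. The package
    generates dated routine-screening schedules for birth-cohort by frequency
    by modality by delay scenario grids, simulates individual life courses
    under cytology-based or primary HPV-based screening with imperfect
    colposcopy and treatment compliance, and computes short-term
    symptomatic-cancer rate ratios and long-term lifetime risks, excess cases
    per 100,000 women, and percent of cancers prevented. A deterministic
    cohort solver over the identical transition structure serves as a
    verification oracle for the Monte Carlo engine, and a synthetic parameter
    generator ships three natural-history variants with ordered precancer
    dwell times.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
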