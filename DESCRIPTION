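Package: otosignal
Title: Stratified Incidence and Disproportionality Analysis of
    Otolaryngologic Vaccine Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pharmacovigilance pipeline for spontaneous vaccine
    adverse-event reports in the public VAERS three-file layout. Maps
    MedDRA preferred terms to configurable adverse-event groups, computes
    report counts, percentage shares and crude incidence rates per
    100,000 vaccinated persons against external population denominators
    stratified by sex, age band and manufacturer, tests stratum
    differences with Pearson chi-squared or Fisher's exact tests, and
    screens for disproportionate reporting with the proportional
    reporting ratio (PRR) and its log-normal confidence interval. Ships a
    synthetic VAERS-shaped data generator with planted signals and known
    ground truth so every stage is testable without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    yaml,
    jsonlite,
    withr,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
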