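Package: padflow
Title: Treatment-Pathway Mining and Sankey Flow Analysis for Peripheral
    Artery Disease Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining ordered treatment pathways from patient-level
    clinical event logs and relating them to limb-amputation outcomes in
    peripheral artery disease (PAD) cohorts. Reduces raw event tables to
    one first-occurrence treatment sequence per patient (truncated at the
    first amputation), tabulates cohort-normalized pathway rates, computes
    per-pathway odds ratios from 2x2 contingency tables with an
    odds-to-probability conversion, builds stage-indexed and
    outcome-colored Sankey flow graphs with node-level normalization, and
    re-runs the whole pipeline within confounder-defined strata (age, sex,
    race, smoking, comorbidities). Includes a seeded synthetic cohort
    generator that emulates the structure of real electronic health record
    extracts, with configurable pathway mixtures and noise (duplicate
    treatment events, post-outcome events) that extraction must survive.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
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
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
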