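Package: earlyt1d
Title: Polygenic Type 1 Diabetes Analysis for Infants Diagnosed Before 6 Months
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify polygenic type 1 diabetes among infants
    diagnosed with diabetes before 6 months of age. Computes a SNP-weight
    type 1 diabetes genetic risk score (T1D-GRS) from effect-allele dosages,
    classifies individuals against a control-derived centile threshold,
    estimates the excess of high-score individuals over the null expectation
    (the polygenic fraction of a referral cohort), summarises islet
    autoantibody positivity against control-derived cut-offs, applies
    limit-of-detection coding to C-peptide, computes birthweight z-scores
    against a pluggable sex- and gestation-specific growth reference, and
    generates seeded synthetic referral cohorts with the same statistical
    structure for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR,
    generics,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
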