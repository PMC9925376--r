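Package: pgxepi
Title: CYP2C19 Pharmacogenetics and Antidepressant Treatment Outcomes from
    Prescription-Registry Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for pharmacogenetic pharmacoepidemiology with
    prescription-registry data: classification of phased CYP2C19 genotypes
    into star alleles, six-level metabolic phenotypes and an inverted
    activity score (plus the expanded ten-level CYP2C diplotype scheme);
    reconstruction of continuous treatment episodes from pharmacy
    dispensation dates with a maximum-refill-gap rule and a capped
    defined-daily-dose tail; derivation of four analysis-ready treatment
    outcomes (early non-persistence, discontinuation, switching, and
    treatment-emergent mania) with their covariate flags and sensitivity
    variants; cluster-robust Cox and exchangeable-correlation GEE logistic
    inference including an activity-score trend model and nested Wald
    interaction tests; a Schoenfeld-type Cox sample-size calculation; and a
    synthetic registry generator that emulates the joint structure of
    dispensation, admission, genotype and demographic tables so the whole
    chain is testable without access to restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    survival (>= 3.0),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    sandwich
Config/testthat/edition: 3
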