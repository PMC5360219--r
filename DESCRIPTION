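Package: polyhaz
Title: Polygenic Hazard Scores for Age-Dependent Disease Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Derives survival-based polygenic hazard scores (PHS) from GWAS
    candidate variants by forward stepwise Cox selection on martingale
    residuals with bootstrap model averaging, and calibrates the resulting
    score against published population incidence rates to produce
    individualized annualized incidence, survivor curves, and expected ages
    of onset. Includes a synthetic genotype and age-of-onset cohort
    generator (Hardy-Weinberg genotypes, Gompertz baseline hazard,
    proportional polygenic effects, right censoring, case-control
    ascertainment), a reference score distribution built from allele
    frequencies, and replication procedures: percentile risk stratification
    with Kaplan-Meier curves, predicted-versus-empirical onset-age
    correlation, progression-rate trend tests, and decile hazard ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
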