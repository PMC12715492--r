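Package: grscale
Title: Genetic Risk Scales from Matched Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates point-based genetic risk scales in 1:1
    matched case-control studies of biallelic SNPs. Provides carrier-model
    genotype encodings, Hardy-Weinberg equilibrium testing, matched-pair
    association statistics (McNemar tests and discordant-pair odds ratios),
    conditional logistic regression for 1:1 sets fitted from the conditional
    likelihood, a SNP filter cascade with risk-genotype orientation and
    point-score construction, threshold/ROC evaluation with Hanley-McNeil
    confidence intervals, matched-design sample-size calculations, and a
    synthetic matched-cohort generator for validation. Includes the summary
    counts of a motivating study of the no-reflow phenomenon in STEMI
    patients as a worked fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    pROC,
    vcfR,
    knitr,
    withr
Config/testthat/edition: 3
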