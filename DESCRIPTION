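Package: sdbchains
Title: Multi-Omics Association Chains for Sleep-Disordered Breathing Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multi-stage inference linking sleep-disordered breathing (SDB)
    traits, blood cell-type-specific transcript expression, and serum
    metabolites across three cohorts. Implements transcriptome-wide
    association with permutation-based empirical p-values, transcript
    polygenic risk score (tPRS) construction by genome-wide clumping and
    thresholding with validation in an independent cohort, linear mixed
    models with sparse kinship, household, and sampling-block random effects
    estimated by AI-REML, survey-design robust regression for metabolite
    associations, and an association-chain classifier. A synthetic-cohort
    generator with planted causal scenarios (LD-blocked genotypes, cis/trans
    eQTL architecture, skewed apnea-hypopnea-index-like traits, bounded
    oximetry traits, limit-of-detection censored lognormal metabolites,
    sibling relatedness, and probability-sampling weights) provides ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
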