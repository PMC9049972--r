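Package: epiclock
Title: Epigenetic Clocks, Methylome Entropy, and QTL Mapping of Age
    Acceleration in Recombinant Inbred Mouse Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds penalized-regression DNA-methylation clocks with a
    log-linear age transform, derives age-adjusted epigenetic age
    acceleration (EAA), computes methylome-wide Shannon entropy,
    runs multivariable epigenome-wide association (EWAS) with
    differentially methylated CpG classification, maps EAA with a
    kinship-corrected linear mixed model and Fisher meta-analysis,
    estimates strain heritability, and tests annotation enrichment.
    Ships a synthetic-cohort generator for recombinant inbred panels
    (genotype mosaics, lifespans, diet/weight covariates, bimodal
    methylomes with planted age, diet, and QTL effects) so the full
    pipeline is testable end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    lme4,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
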