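Package: gxegreml
Title: Variance-Component Models for Genome-by-Environment Interaction
    with Methylation Exposure Proxies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-component restricted maximum likelihood (GREML) analysis
    of quantitative traits with gene-by-environment interaction random
    effects.  Builds genomic, kinship, categorical-environment and
    methylation-derived relationship matrices, combines them through
    Hadamard products into interaction covariances, fits them by
    average-information REML with boundary-aware likelihood-ratio tests,
    pools sub-cohort estimates by inverse-variance meta-analysis, and ships
    a synthetic-cohort generator (family-structured genotypes, smoking
    exposure, smoking-driven CpG methylation) so every stage can be
    exercised and calibrated without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    metafor,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
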