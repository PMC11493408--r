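Package: dgrpanel
Title: Harmonized Phenomics and Association Analytics for Inbred Reference Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with harmonized line-by-phenotype data from
    inbred reference panels such as the Drosophila Genetic Reference Panel
    (DGRP): strict TSV input/output following community data-sharing
    guidelines, a seeded synthetic-panel generator (genotypes, covariates,
    block-correlated multi-study phenotypes), sex-stratified cross-study
    Spearman correlation with Benjamini-Hochberg FDR control,
    covariate-adjusted per-variant linear association with rank-based
    inverse-normal transformation and phenome-wide (PheWAS) lookup, and a
    rank-based fraction-of-extremeness score for flagging outlier lines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
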