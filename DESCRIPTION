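Package: BrainTxMap
Title: Disease-Related Brain Transcriptome Mapping
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-stage identification of disease-related genes by brain
    transcriptome mapping. Stage 1 estimates per-region diagnostic effects
    on an imaging trait (e.g. amyloid-PET SUVR parcellated on a
    HCPMMP-style cortical atlas) with covariate-adjusted linear regression,
    producing per-contrast significance maps. Stage 2 spatially correlates
    brain-wide gene expression maps (AHBA-style, left hemisphere) with
    those imaging-diagnosis maps, applies Bonferroni family-wise error
    control over the pooled gene-by-contrast family, intersects findings
    across contrasts, and partitions them into known and novel genes by a
    user-supplied disease annotation list. A synthetic-cohort module
    generates phenotype, imaging and expression data with the statistical
    structure the analysis assumes, including a ground-truth record, so
    the whole pipeline is testable without restricted-access downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    pheatmap,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, Regression, Software
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'BrainTxMap-package.R'
    'diagnosis.R'
    'correlation.R'
    'io.R'
    'simulate.R'
    'pipeline.R'
    'reporting.R'
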