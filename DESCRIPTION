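Package: popExpVar
Title: Population Transcriptome Expression Variation Across Environments
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of gene expression variation in plant populations
    transplanted between common-garden environments. Computes per-gene
    population expression level (Ep) and expression diversity (Ed) in each
    environment, cross-environment expression variation (Ep ratio, Ed
    change) with conservation classification, gene-level nucleotide
    diversity (pi) from transcriptome SNPs, EM-based haplotype phasing for
    low-SNP genes, and two-way fixed-effect ANOVA partitioning expression
    variation into environment, population/haplotype and interaction
    effects with positive-FDR control. Includes a synthetic-data generator
    emulating a 14-population by 2-environment transplant design so every
    stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'effects.R'
    'expression-stats.R'
    'io.R'
    'phasing.R'
    'popgen.R'
    'simulate.R'
    'pipeline.R'
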