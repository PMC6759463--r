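Package: gbspop
Title: Population Structure, Differentiation and Association Analysis for
    Genotyping-by-Sequencing Germplasm Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-genotyping analysis toolkit for biallelic SNP panels from
    genotyping-by-sequencing of inbred (selfing) crop germplasm. Provides
    genotype input/output (VCF, HapMap-style and plain 0/1/2 tables), SNP and
    sample quality-control filtering with transition/transversion summaries,
    linkage-disequilibrium pruning, identity-by-state duplicate detection with
    replicate-calibrated thresholds, population-structure inference by k-means
    with Bayesian Information Criterion model selection, discriminant analysis
    of principal components with cross-validation, an admixture model fitted by
    expectation-maximisation with Evanno delta-K model selection,
    Weir-Cockerham F_ST estimation (pairwise and per-locus one-vs-rest),
    Nei distances with neighbour-joining trees and locus bootstrap,
    allele-sharing Ward dendrograms, randomised-complete-block phenotype
    statistics (ANOVA, broad-sense heritability, Tukey HSD with compact letter
    displays) and kinship mixed-model genome-wide association with multi-locus
    forward selection. Includes a Balding-Nichols synthetic-data generator so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    car,
    dplyr,
    generics,
    ggplot2,
    igraph,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    phangorn,
    withr
Config/testthat/edition: 3
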