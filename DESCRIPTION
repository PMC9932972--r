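Package: polycore
Title: Dosage-Based Diversity Analysis and Breeder Subset Selection for
    Autopolyploid Germplasm Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for post-variant-calling analysis of allele-dosage
    genotypes from autopolyploid germplasm collections such as hexaploid
    sweetpotato. Provides marker quality control and composite linkage
    disequilibrium pruning on integer dosage calls, per-population
    diversity indices (PIC, effective alleles, rarefied allelic richness,
    Shannon index, private alleles), Hudson-type Fst and Nei's (1972)
    standard genetic distance, a full-autopolyploid genomic relationship
    matrix with UPGMA clustering, PCA / K-means-BIC / DAPC population
    structure analysis, rare-phenotype flagging of descriptor tables, and
    an iterative multi-criteria procedure that selects nested breeder
    germplasm subsets preserving both genotypic cluster coverage and
    phenotypic diversity. A seedable synthetic-collection generator
    (Balding-Nichols differentiation, within-chromosome LD decay,
    mixed-type trait tables) makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    vcfR
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
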