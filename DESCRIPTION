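Package: PathwayEpistasis
Title: Pathway-Level Genetic Interaction Discovery from Case-Control GWAS
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Discovers pathway-level genetic interactions from case-control
    genotype data. SNP-SNP interactions are scored under dominant and
    recessive disease models with an exact hypergeometric statistic (hygeSSI)
    or under an additive model with a logistic-regression likelihood-ratio
    test. Interaction networks are binarized at a target density and scanned
    for between-pathway (BPM), within-pathway (WPM) and hub-pathway (PATH)
    structures, whose significance is assessed by SNP-pathway membership
    permutations and a hybrid sample-permutation false discovery rate.
    Includes genotype quality control (missingness, minor allele frequency,
    Hardy-Weinberg, relatedness, case-control matching, LD pruning),
    SNP-to-pathway mapping, replication analysis against independent cohorts,
    and synthetic-cohort and synthetic-network simulators that support a
    two-stage statistical power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
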