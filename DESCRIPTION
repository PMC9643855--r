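Package: snpmdr
Title: Case-Control SNP Association and Multifactor Dimensionality
    Reduction for Gene-Gene Interaction Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting single-locus and epistatic (gene-gene)
    effects of SNPs on binary disease outcomes in case-control cohorts.
    Provides per-SNP association statistics under five inheritance models
    (codominant, dominant, recessive, over-dominant, additive) with crude
    and covariate-adjusted odds ratios, Hardy-Weinberg equilibrium testing
    (asymptotic and exact), quality-control filters (minor allele
    frequency, HWE, linkage-disequilibrium pruning), a multifactor
    dimensionality reduction (MDR) engine with stratified cross-validation,
    permutation testing and high-risk genotype listing, entropy-based
    interaction-information scoring with synergy/redundancy network and
    dendrogram export, and a penetrance-model cohort simulator for
    validating the whole chain on data with known genetic architecture.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
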