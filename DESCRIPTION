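Package: clinepop
Title: Contact-Zone Population Genetics: Diversity Statistics, Haplotype
    Networks, Geographic Clines and Distribution-Model Support
Version: 0.2.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrative analysis of avian contact zones from mitochondrial
    sequences, microsatellite genotypes, morphometric traits and admixture
    scores. Provides nucleotide diversity, Watterson and pairwise theta,
    Tajima's D and Fu's Fs neutrality tests with simulation-based nulls,
    minimum-spanning haplotype networks, between-clade raw divergence and
    strict-clock age conversion; microsatellite heterozygosity, exact
    Hardy-Weinberg tests, hypergeometric allelic-richness rarefaction,
    private-allele reports, genotypic linkage-disequilibrium tests and
    DAPC-style assignment; geographic cline fitting for frequency and
    quantitative traits with sigmoid plus exponential-tail architectures,
    adaptive MCMC and AICc model selection over fifteen architectures;
    ordination and cross-validated discriminant classification; bias-aware
    pseudo-absence sampling, tuning-grid enumeration and
    permutation-importance backward selection for distribution models; and
    seeded generators for coalescent sequence panels, Balding-Nichols
    genotypes, transects and landscape grids with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    MASS,
    glmnet,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
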