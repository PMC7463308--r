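Package: relictgen
Title: Population Genomic Inference for Relict Tree Phylogeography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for RAD-SNP phylogeography of fragmented
    relict tree species: genotype-matrix import and locus filtering,
    per-population diversity and hierarchical AMOVA with permutation tests,
    coalescent simulation of divergence and demographic scenarios,
    approximate Bayesian computation (scenario choice, cross-validation, and
    local-linear parameter estimation), Bayesian and island-model FST outlier
    scans, multiple-regression environment association, generalized
    dissimilarity modelling of pairwise PhiST with I-splines and backward
    elimination, and gradient-forest prediction of genomic vulnerability to
    future climate. Includes a synthetic-data generator with known truth so
    every stage can be exercised end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    splines,
    nnet,
    pracma,
    geosphere,
    randomForest,
    vcfR,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
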