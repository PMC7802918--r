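Package: treecure
Title: Phylogeny-Guided Revision of Transcript-to-Gene Assignments
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects transcriptome-assembly errors in which transcripts of a
    single gene were assigned to several spurious genes, by locating
    improbably short same-species subtrees in gene phylogenies. A
    two-component mixture model on duplication times (a gamma component for
    spurious splits and a constant-rate birth-death component for true
    duplications), fitted by Gibbs sampling, selects the subtree-length
    threshold by Bayesian decision theory; flagged gene sets are merged into
    a revised transcript catalog. Includes a gene-family birth-death
    simulator with controlled misassignment injection, and clustering
    evaluation statistics (adjusted Rand index, pairwise precision/recall,
    Kolmogorov-Smirnov and Kullback-Leibler comparisons of duplication-time
    distributions).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    mclust,
    igraph,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Phylogenetics, Transcriptomics, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'flagging.R'
    'evalmetrics.R'
    'timing.R'
    'mixture.R'
    'treeio.R'
    'synthdata.R'
    'treecure-package.R'
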