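Package: hypwas
Title: Hyperspectral Wide Association and Machine-Learning GWAS for Yield Traits
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Hierarchical phenome-to-genome association toolkit for plant
    breeding trials. Preprocesses proximal-sensing hyperspectral reflectance
    (band trimming, rebinning, Savitzky-Golay smoothing, PCA outlier screen),
    fits multi-environment mixed models (REML variance components, BLUP,
    entry-mean heritability), selects yield-associated reflectance bands by
    cross-validated recursive feature elimination (HypWAS), and maps selected
    bands to the genome with three GWAS engines: a kinship mixed linear model
    (P3D), an iterative fixed/random pseudo-QTN scan (FarmCPU style), and a
    support-vector-regression importance scan with a permutation-based global
    empirical significance threshold. Post-GWAS utilities cover FDR control,
    LD decay, peak flanking regions, allelic effects, and gene-interval
    overlap from GFF3 annotation. Includes a fully parameterised synthetic
    data generator with planted causal structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    data.table,
    jsonlite,
    lme4,
    Rcpp,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
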