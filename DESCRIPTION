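Package: rvrobust
Title: Robust Adaptive Sum of Powered Score Tests for Rare-Variant
    Association with Quantitative Traits
Version: 0.1.0
Authors@R: person("rvrobust", "maintainers", email = "rvrobust@example.org",
    role = c("aut", "cre"))
Description: Set-based (gene-based) rare-variant association tests for
    quantitative traits built on the score vector of the linear model:
    the sum of powered score SPU(gamma) family, the adaptive aSPU
    combination, and their Huber-loss robust counterparts SPUr/aSPUr that
    remain calibrated under heavy-tailed, skewed, or contaminated trait
    distributions.  Includes burden (T1) and asymptotic linear-kernel
    SKAT comparators, residual-permutation and parametric-bootstrap
    p-values with a stage-wise adaptive number of resamples,
    genomic-control diagnostics, trait transforms (log, rank-based
    inverse-normal, Winsorizing, trimming), a latent-Gaussian haplotype
    simulator for rare variants, and drivers that regenerate the
    type-I-error and power simulation grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    jsonlite,
    withr
Config/testthat/edition: 3
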