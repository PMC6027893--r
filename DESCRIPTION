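Package: gxepredict
Title: Genomic Prediction Under Genotype-by-Environment Interaction in
    Multi-Environment Breeding Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for breeding under genotype-by-environment interaction
    (GxE) in two-environment trials, modelled on water-management contrasts
    in rice (continuous flooding versus alternate wetting and drying).
    Provides a synthetic trial generator with a controllable
    cross-environment genetic correlation; REML mixed-model phenotype
    adjustment with broad-sense heritability, conditional R2, genetic
    correlations with Fisher confidence intervals and correlated-response
    ratios; genotypic response variables (relative-performance index and
    joint-regression slope); marker-based linear and Gaussian kernels with
    empirical-Bayes bandwidth estimation; Bayesian kernel regression by
    Gibbs sampling for single-environment GBLUP/RKHS and three
    multi-environment extensions; and an evaluation framework covering
    M1/M2 cross-validation, progeny validation scenarios with CDmean
    training-set optimization, predictive-ability computation and
    Z-transformed factorial analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    coda,
    vcfR,
    jsonlite,
    withr
Config/testthat/edition: 3
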