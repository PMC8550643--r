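Package: transcorr
Title: Trans-Ancestral Genetic Correlation and Heritability from GWAS
    Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and estimation toolkit for trans-ancestral genetic
    correlation. Simulates pairs of ancestrally diverged populations (and
    two-way admixed populations) with distance-decaying linkage
    disequilibrium, draws correlated per-SNP effect sizes from a bivariate
    spike-and-slab model, produces GWAS summary statistics, computes
    within- and cross-population LD scores from external reference panels,
    and estimates SNP heritability and genetic correlation by maximizing an
    approximate weighted likelihood on observed Z statistics with
    block-jackknife standard errors. Includes an evaluation harness that
    measures bias and stability of the estimates across sweeps of sample
    size, SNP count, reference-panel size, panel misspecification, and
    admixture.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
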