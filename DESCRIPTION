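Package: rilgs
Title: Genomic Selection and Quantitative Genetics for Connected RIL Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for multi-environment trials of
    connected recombinant inbred line (RIL) populations, modeled on autumn-sown
    field pea breeding programs. Provides a genetic simulator (Haldane meiosis,
    single-seed descent, genotype-by-environment interaction with exact
    finite-sample variance targeting), GBS-style marker quality control and
    imputation, balanced expected-mean-squares and REML variance component
    estimation with broad-sense heritability, BLUP and genetic correlations,
    whole-genome regression (ridge-regression BLUP with spectral REML, and
    Gibbs samplers for Bayesian A, Bayesian C and the Bayesian Lasso),
    intra- and inter-population inter-environment cross-validation of
    predictive ability, kinship- and principal-component-corrected genome-wide
    association scans, and a breeder's-equation calculator comparing genomic
    and phenotypic selection efficiency under cost constraints.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    lme4,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
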