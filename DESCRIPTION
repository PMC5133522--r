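Package: rarelogit
Title: Sparse-Data Single-Variant and Variant-Collapsing Association Tests
    for Binary Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Association tests for rare and low-frequency genetic variants
    with a binary outcome under covariate adjustment: standard and
    Firth-penalized logistic likelihood-ratio tests, standard and
    small-sample moment-adjusted score tests, and region-level
    variant-collapsing tests (MAF-weighted burden, SKAT, SKAT-O) with
    chi-square-mixture tail probabilities by characteristic-function
    inversion.  Includes a synthetic genotype-dosage and phenotype
    generator emulating a single-gene exonic variant panel, and a
    replicate-based evaluation driver for carrier-count-pooled type I
    error and per-variant / per-subregion power.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
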