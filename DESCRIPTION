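Package: pwmr
Title: Phenome-Wide Mendelian Randomization with Tree-Structured Bayesian Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for phenome-wide mendelian randomization of a continuous
    exposure proxied by a weighted genetic risk score. Builds a phecode-based
    phenome from ICD-coded diagnosis records with control-exclusion ranges,
    runs per-phenotype logistic regressions with false-discovery-rate control,
    scans the ICD-10 classification tree with a Bayesian Markov model of
    evolving genetic coefficients solved by exact belief propagation,
    replicates findings with a two-sample mendelian randomization estimator
    suite (inverse-variance weighted, Egger, weighted median, mode-based) with
    pleiotropy diagnostics, and dissects instrument pleiotropy through
    stratified and leave-group-out risk scores. A synthetic biobank generator
    with a liability-threshold disease model supports testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
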