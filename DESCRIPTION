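Package: pooldecode
Title: Decoding Genotypes and Fusion-Gene Carriers from Overlapping
    Sequencing Pools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Design and decoding of overlapping-pool sequencing
    experiments, in which the DNA or RNA of many individuals is mixed
    into a small number of pools and pool-level read counts are
    deconvoluted back to individual samples.  Provides construction and
    local-search optimization of binary pooling designs together with
    information-theoretic lower bounds on the number of pools; a
    Gamma-Poisson simulator of pooled read counts with concentration
    jitter and sequencing error, including calibrated synthetic
    imputation priors; a composite likelihood combining Hardy-Weinberg,
    Poisson read-count and imputation terms; linear-programming decoders
    for common variants (anchored on imputation dosages) and rare
    variants (anchored on zero); least-squares calibration of pool
    concentrations from known genotypes; and an enumeration plus
    least-squares screen with likelihood grid refinement for detecting
    fusion-gene carriers in pooled tumor RNA with unknown per-sample
    expression levels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    pracma,
    quantreg,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    boot,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
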