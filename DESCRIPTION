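Package: fcpipe
Title: Simulation and Benchmarking of EEG Source Connectivity Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates pseudo-EEG sensor recordings with ground-truth
    inter-regional interactions from an analytic three-shell spherical head
    model, and benchmarks source-reconstruction (eLORETA, LCMV, DICS,
    Champagne), region-aggregation (PCA and related schemes) and
    functional-connectivity pipelines (coherence, imaginary coherency, MIM,
    MIC, multivariate spectral Granger causality and its time-reversed
    variant) with a normalized percentile-rank score and surrogate
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
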