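Package: dualrc
Title: Unsupervised Chunking of Information Streams with Dual Reservoir Computing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a pair of chaotic rate-network reservoirs whose linear
    readouts supervise each other, so that the joint system learns, without any
    external teacher, to signal frequently recurring segments ("chunks") of a
    temporal input stream. Provides generators for annotated symbol streams,
    community-graph random walks and image streams; difference-of-exponentials
    input encoding; FORCE (recursive least squares) training of the readouts
    against rectified-sigmoid teaching signals built from the partner module's
    normalized output; and analysis tools for chunk-detection performance,
    reservoir selectivity, principal-component diagnostics and readout-weight
    statistics. The millisecond-resolution network integration runs in compiled
    code.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    png,
    withr,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
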