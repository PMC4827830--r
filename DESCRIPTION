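Package: olfcs
Title: Feedforward Compressed Sensing of Sparse Odor Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Codec, closed-form theory, and simulation toolkit for a
    feedforward compressed-sensing model of the olfactory system. Sparse
    binary odor vectors are OR-encoded into glomerular activity through a
    random binary affinity matrix and AND-decoded by third-order neurons.
    Provides the analytic false-detection rate, the optimal glomerulus to
    third-order-neuron connectivity 1/(K+1), reconstruction SNR, mutual
    information of the sparse binary channel, compression-ratio limits,
    Monte-Carlo verification and robustness experiments (stuck-on and
    ablated glomeruli, recovery-threshold sweeps), a LASSO/pseudo-inverse
    baseline comparison, and the continuous min-operator extension with a
    spiking (LIF plus short-term depression) demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
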