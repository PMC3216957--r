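Package: spikete
Title: Transfer Entropy and Cross-Correlation Measures of Effective
    Connectivity Between Spiking Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies effective (directed) connectivity between spiking
    neurons from binned binary spike trains.  Implements delay-one transfer
    entropy, delayed transfer entropy evaluated across a grid of candidate
    synaptic delays, and higher-order transfer entropy with multi-bin
    message lengths, all computed with a sparse pattern-counting algorithm,
    together with two normalized cross-correlation variants.  Delay profiles
    are collapsed to connection scores by peak value or coincidence index.
    Ships a 1000-neuron Izhikevich cortical network simulator with
    spike-timing-dependent plasticity, conduction delays and Poisson
    thalamic drive that provides ground-truth synaptic wiring, and an
    ROC-based evaluation framework (true/false positive rates, purity,
    identified-weight fraction, recording-length / bin-size / order sweeps)
    for benchmarking connectivity measures against the known wiring.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
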