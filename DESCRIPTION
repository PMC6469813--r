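Package: croscillations
Title: Critical Oscillations Lattice Model and Neuronal Avalanche Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates a two-dimensional disordered network of excitatory and
    inhibitory stochastic spiking neurons (the CROS, "CRitical OScillations",
    model) and provides the analysis battery used to probe neuronal
    criticality at the emergence of collective oscillations: threshold-based
    avalanche extraction, the kappa scale-invariance index, maximum-likelihood
    fitting of exponentially truncated power laws with loglikelihood-ratio
    model comparison, a spectral order parameter, detrended fluctuation
    analysis of raw and band-filtered activity, avalanche shape collapse and
    crackling-noise scaling-relation tests, plus seeded synthetic generators
    with known ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
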