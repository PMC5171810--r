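Package: spikeinfo
Title: Spectral Mutual Information in Spike Trains from Pairwise Correlations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates the mutual information rate between a stimulus and the
    spike train of a single neuron from two pairwise spike statistics: the
    spike autocorrelation within trials and the trial cross-correlation
    (equivalently, the autocorrelation of the peristimulus time histogram)
    measured under frozen-stimulus repeats. Information is computed per
    frequency from the variance ratio of trial Fourier coefficients and
    integrated into bits per second and bits per spike. The package also
    implements comparison estimators (coherence-style lower bound, a
    PSTH-based Poisson approximation, interspike-interval information and
    the binary-word direct method), diagnostics for the underlying Fourier
    statistics (complex Gaussianity, Rayleigh amplitudes, uniform phases),
    simulators for four stochastic spiking neuron models (threshold-based
    level crossing, leaky, adaptive and exponential integrate-and-fire)
    driven by Ornstein-Uhlenbeck or bimodal input currents, and drivers that
    chain these pieces into reproducible sweep experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
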