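Package: ripplenet
Title: Inhibition-First Modeling of Hippocampal Ripple Oscillations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and mean-field theory of hippocampal sharp wave-ripple
    oscillations generated by a delayed, pulse-coupled network of noisy leaky
    integrate-and-fire interneurons. Provides the spiking-network simulator,
    ripple metrics including instantaneous-frequency estimators and the
    intra-ripple frequency accommodation (IFA) slope, the Gaussian-drift
    delay-differential-equation reduction with closed-form constant-drive and
    linear-drive cycle theories, and the Fokker-Planck linear stability
    analysis locating the Hopf bifurcation via the exact leaky
    integrate-and-fire susceptibility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
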