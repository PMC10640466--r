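Package: critnet
Title: Excitation-Inhibition Balanced Spiking Networks at Criticality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates small dense networks of conductance-based leaky
    integrate-and-fire neurons with excitatory and inhibitory synapses under
    Poisson background drive and alpha-function stimuli, and analyses the
    resulting activity at several levels: neuronal-avalanche detection with
    doubly truncated discrete power-law fitting and a truncation-based
    Kolmogorov-Smirnov surrogate test, local-field-potential power spectra and
    Morlet wavelet time-frequency maps, event-related potentials and
    alpha-band desynchronization, peristimulus time histograms, and inter-spike
    interval variability (CV and Fano factor). Includes synthetic-data
    generators and brute-force oracles for testing every analysis step.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    deSolve
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
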