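Package: dendrhythm
Title: Rhythmic Inhibition and Dendritic Integration in a Model Layer 5
    Pyramidal Neuron
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates how spatially targeted (perisomatic versus distal
    dendritic) and rhythmically modulated (beta versus gamma) synaptic
    inhibition shapes dendritic integration in a conductance-based
    multicompartment layer 5 pyramidal neuron. Provides generators for
    naturalistic presynaptic drive (1/f-modulated inhomogeneous Poisson
    spike trains organised into functional groups, lagged feedforward
    inhibition, sinusoidal and bursty rhythms, jittered clustered inputs),
    AMPA/NMDA/GABA-A synapses with magnesium block and two-factor
    short-term depression, a Hines-ordered implicit cable solver with ten
    Hodgkin-Huxley conductances, detectors for somatic action potentials
    and dendritic Na+, NMDA, and Ca2+ spikes, and the accompanying
    analytics: spike-triggered averages, phase histograms, pairwise phase
    consistency, phase-stratified corrected cross-correlograms, and f-I
    curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
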