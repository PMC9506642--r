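Package: ihcable
Title: Compartmental Simulation of HCN-Channel Effects on Pyramidal-Cell
    Excitability
Version: 0.1.0
Authors@R:
    person("Ihcable", "Developers", email = "ihcable@example.org",
           role = c("aut", "cre"))
Description: A multicompartment cable-equation simulator for studying how
    hyperpolarization-activated (HCN, Ih) channels shape the excitability of
    thick-tufted layer V pyramidal cells.  Implements Hodgkin-Huxley style
    channel kinetics for two published Ih variants and a low-voltage-activated
    (T-type) calcium channel, an intracellular calcium pool with dynamic
    Nernst reversal, distance-dependent conductance profiles including an
    apical calcium-channel hot zone, neuromodulation operators that shift the
    Ih half-activation voltage, current- and conductance-based stimuli
    (square pulses, alpha synapses, AMPA/NMDA/GABA receptors, seeded synapse
    populations), and the experiment protocols built on top of them: f-I
    curves, bisection threshold search, distance sweeps, distributed-synapse
    grids with Mann-Whitney statistics, combined basal/apical stimulation and
    split proximal/distal neuromodulation.  Stylized ball-and-tuft
    morphologies make every protocol runnable at desk scale without external
    reconstructions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
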