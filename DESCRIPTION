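Package: neurowire
Title: Topography-Driven Neuronal Network Topology, Energetics and Information Flow
Version: 0.1.0
Authors@R:
    person("Neurowire", "Developers", email = "neurowire@example.org",
           role = c("aut", "cre"))
Description: Analysis chain linking nanostructured substrate topography to the
    architecture and function of cultured neuronal networks.  Provides
    power-spectral surface characterization (radial power spectrum, fractal
    dimension via the slope relation Df = (8 - beta)/2, average roughness,
    Abbott-Firestone bearing curve, solid fraction), Waxman random spatial
    graph reconstruction from cell-nucleus positions, small-world network
    metrics with Erdos-Renyi baselines, density-peak supercluster detection
    (Rodriguez-Laio decision graph), ghost-cell potential-energy landscapes
    of clustered cell configurations, leaky integrate-and-fire simulation
    with Shannon-information readout, and calcium-fluorescence spike-onset
    analysis.  Includes seeded synthetic-data generators (self-affine
    surfaces, nanowire top views, clustered cell fields, nuclei images,
    calcium traces) so the whole pipeline is testable without experimental
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
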