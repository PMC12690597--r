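Package: polyplexmd
Title: Coarse-Grained Molecular Dynamics of Polyplex Self-Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Bead-spring molecular dynamics of RNA-polycation (polyplex)
    self-assembly in reduced Lennard-Jones units, with full periodic
    electrostatics by Ewald summation, a leapfrog integrator with the
    stochastic velocity-rescaling thermostat, and an analysis suite for
    the resulting nanoparticles: cluster detection, gyration-tensor shape
    metrics, Kirkwood hydrodynamic radius, charge decomposition,
    zeta-potential from radial cumulative-charge profiles, Manning
    counterion-condensation fractions, cluster-count order parameters,
    free-energy profiles, and charge-ratio scaling transforms.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
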