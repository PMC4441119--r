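Package: ktnet
Title: Energy Landscapes and Kinetic Transition Networks for Disordered Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for the energy-landscape analysis of
    intrinsically disordered peptides: basin-hopping global optimisation,
    doubly-nudged elastic band and eigenvector-following transition-state
    searches, kinetic transition network (stationary-point database)
    construction and refinement, harmonic-superposition thermodynamics,
    graph-transformation phenomenological rate constants, disconnectivity
    graphs, parallel-tempering Monte Carlo with MBAR reweighting, and
    conformational/sequence order parameters (helicity, radius of gyration,
    contact maps, dihedral clustering, charge-patterning kappa). Ships
    analytic test surfaces (Muller-Brown, Lennard-Jones clusters, a 1-D
    double well) and a coarse-grained charged bead-peptide model emulating
    the multifunnel landscape of a disordered BH3 peptide.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    grDevices,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
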