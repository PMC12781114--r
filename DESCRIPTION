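Package: nqogate
Title: Conformational Gating and Kinetic Analysis of NADH:Quinone Oxidoreductase Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for loop-3 gating in flavin-dependent
    NADH:quinone oxidoreductase (NQO). Provides trajectory handling
    (PDB/DCD/XYZ input, atom selection, Kabsch superposition, RMSD),
    ensemble principal component analysis with scree, projections, 2D
    conformational densities and most-probable-state extraction,
    heavy-atom residue contact probabilities with difference contact
    network analysis (dCNA) and consensus community detection, gate
    residue-pair distance statistics, and nonlinear least-squares fits of
    ping-pong bi-bi steady-state kinetics (with and without NADH
    substrate inhibition), stopped-flow biexponential transients, and
    hyperbolic kobs saturation. Includes seeded synthetic-data generators
    for two-state open/closed gate ensembles and simulated kinetic
    datasets, and a configuration-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    minpack.lm,
    igraph,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
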