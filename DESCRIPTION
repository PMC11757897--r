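Package: hemonet
Title: Multiple Flow Equilibria in Microvascular Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady-state modelling of blood flow with haematocrit transport in
    small microvascular networks. Vessels follow Poiseuille's law with the in-vivo
    apparent-viscosity relation of Pries et al. (Fahraeus-Lindqvist effect), and
    red-blood-cell phase separation at bifurcations is modelled by the Pries 1990
    plasma-skimming rule behind a pluggable rule interface. The package assembles
    the dimensionless nonlinear network equations, solves them by damped Newton
    iteration and homotopy continuation, traces equilibrium branches in any network
    parameter by pseudo-arclength continuation with fold-bifurcation detection, and
    classifies coexisting equilibria by the flow state (negative, intermediate,
    positive) in each redundant vessel. Includes the canonical triangle and
    extended-triangle benchmark networks, a random small-network generator for
    property testing, a JSON network format, and sweep drivers that map how the
    number of equilibria depends on vessel length ratios, diameters and inlet
    haematocrit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    lhs,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
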