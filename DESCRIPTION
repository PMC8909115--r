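Package: tribochar
Title: Tribocharging-Based Characterization of Powders in Particle-Laden
    Pipe Flows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and inversion toolkit for triboelectric powder
    characterization in dilute gas-solid pipe flows. Provides analytic
    fully-developed pipe flow profiles with standard turbulence
    correlations, a seeded Lagrangian particle tracker (Schiller-Naumann
    drag, gravity, discrete-random-walk turbulent dispersion, specular
    wall bounces) that computes particle-wall collision statistics, the
    condenser-model algebra mapping collision numbers to charge-to-mass
    ratios and back to contact potential differences, a feed-forward
    neural-network surrogate for fast collision-number prediction, and a
    characterization pipeline that couples measured charge-to-mass ratios
    of sieved powder fractions to simulated collision statistics to
    estimate composition-sensitive contact potential differences.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    nnet,
    jsonlite,
    yaml,
    lhs,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
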