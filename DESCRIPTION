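Package: decompevo
Title: Multi-Scale Eco-Evolutionary Simulation of Microbial Soil Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid stochastic-deterministic simulation of microbial
    decomposition of soil organic carbon, where decomposition is a spatial
    public-goods game played by exoenzyme-producing cells. Within a microsite,
    soil organic carbon (SOC), dissolved organic carbon (DOC) and exoenzymes
    follow deterministic mass-balance flows while a finite cell population
    grows by threshold division and dies stochastically (a piecewise
    deterministic Markov process). Microsites are coupled on a square lattice
    by DOC diffusion (explicit Euler scheme, Neumann boundaries), newborn
    dispersal and micro-disturbances. The exoenzyme allocation fraction is an
    evolving trait: the package provides mutation at division, resident-mutant
    invasion contests, bracketing of evolutionarily stable strategies across
    soil diffusivities, and ecosystem-function read-outs (decomposition rate
    and SOC stock), together with the deterministic four-compartment
    approximation, its steady states and the analytic selection gradient.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    stats,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
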