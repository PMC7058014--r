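Package: samcascade
Title: Multicellular Simulation of the Epidermal miR171-HAM Patterning
    Cascade in the Shoot Apical Meristem
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds dome-shaped 3D cell templates of the Arabidopsis shoot
    apical meristem from overlapping spheres, simulates a five-species
    reaction-diffusion model of the epidermis-derived ATML1/PDF2 ->
    miR171 -> HAM signalling cascade to steady state with an explicit
    forward-Euler scheme on the cell neighbourhood graph, classifies the
    resulting HAM mRNA expression patterns (apical-low/basal-high gradient,
    ectopic-activation suppression), and explores parameter space with a
    one-at-a-time grid, a quasi-Monte-Carlo log-uniform random search, and
    normalized local sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
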