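Package: biofilmsim
Title: Individual-Based Simulation of Microbial Biofilms with
    Thermodynamic Yields, Chemical Speciation and Reactor Coupling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A three-dimensional individual-based model of microbial
    biofilms. Growth yields are predicted from Gibbs energy balances
    between catabolism, anabolism and dissipation; acid-base speciation
    and pH are resolved per grid cell by a charge-balance Newton solver;
    solute transport is explicit finite-difference diffusion-reaction on
    a regular grid with a moving boundary layer; the biofilm is coupled
    to a stirred-tank reactor and a gas headspace via two-film transfer;
    cell-cell overlaps are relaxed by soft-sphere discrete-element
    mechanics. Ships ready-made nitrification and anaerobic-digestion
    scenarios at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
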