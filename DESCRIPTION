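Package: coopbind
Title: Phenomenological Modeling of Cooperative Ligand Binding to
    Two-Site Macromolecules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic mass-action simulation of ligand binding to a
    macromolecule carrying two binding sites, construction of equilibrium
    binding isotherms from kinetic time courses, Hill-coefficient
    estimation via Wyman Hill plots, association and site-interaction
    free energies, the exact equilibrium equivalence between negative
    cooperativity and two independent classes of sites together with its
    kinetic discrimination, and analysis of binding sites hidden by
    strong negative cooperativity.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
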