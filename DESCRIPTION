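Package: crnstationary
Title: Product-Form Stationary Distributions for Stochastic Reaction Networks
Version: 0.1.0
Authors@R:
    person("crnstationary", "maintainers", email = "crnstationary@example.org",
           role = c("aut", "cre"))
Description: Tools for stochastically modeled chemical reaction networks with
    mass-action and theta-product (non-mass-action) kinetics. Computes the
    structural quantities of chemical reaction network theory (complexes,
    linkage classes, weak reversibility, deficiency, conservation laws, the
    per-species alpha-partition of source stoichiometries), complex-balanced
    equilibria of the associated deterministic mass-action system, and the
    product-form invariant measures that these equilibria parameterize for
    networks whose intensity functions factor through per-species theta
    functions on an alpha-strided lattice. Includes ground-truth machinery
    (sparse truncated-generator stationary solves, stationarity residuals,
    Gillespie simulation) and multiscale averaging reductions
    (quasi-equilibrium and constrained averaging) with distribution
    comparison utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
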