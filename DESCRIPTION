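Package: chapcomp
Title: Chaperone-Competition Model of Cell-Cycle Entry in Budding Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic model of competition between bulk protein folding and the
    G1 cyclin Cln3 for the Hsp40 co-chaperone Ydj1 in budding yeast, and its
    consequences for cell size at Start. Provides the seven-variable ODE system,
    exact and integration-based steady states, the weighted-average chaperone
    diffusion observable, critical-budding-volume prediction as a function of
    growth rate, least-squares and affine-invariant ensemble MCMC parameter
    estimation, cycloheximide and stress perturbation simulations, single-cell
    photokinetics estimators (FLIP import/export rates, FCS anomalous-diffusion
    fits, nuclear/cytoplasmic concentration correction, mobility index), seeded
    synthetic-data generators for all inputs, and SBML Level 3 export/import.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    xml2,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
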