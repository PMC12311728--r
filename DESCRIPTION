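Package: amoxkin
Title: Kinetic Modeling of Enzymatic Amoxicillin Synthesis in Batch Reactors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling the kinetically controlled synthesis of
    amoxicillin by penicillin G acylase (PGA) in a batch reactor. Implements
    two competing kinetic models (a Michaelis-Menten formulation with
    competitive inhibition and an equilibrium/elementary-step formulation),
    stiff ODE simulation of four-species concentration time courses,
    variance-based global sensitivity analysis (Saltelli sampling, Sobol
    first- and total-order indices with bootstrap confidence intervals and
    temporal gradients), Metropolis-Hastings MCMC parameter estimation,
    synthetic batch-experiment generation, leave-one-experiment-out
    cross-validation, and rRMSE/AIC/BIC model comparison.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
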