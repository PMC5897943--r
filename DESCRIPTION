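Package: pd1tree
Title: Decision-Tree Prediction of PD-1 Immunotherapy Response from
    Simulated Molecular Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts non-small cell lung cancer response to PD-1 checkpoint
    blockade from patient-specific molecule expression profiles. Implements
    percent-change expression metrics against a non-tumorigenic baseline, a
    weighted dendritic-cell infiltration index over nine chemokines, a
    three-step threshold decision tree over PD-L1, the infiltration index and
    fourteen immunosuppressive molecules, and concordance statistics (match
    scores, responder rates, Fisher's exact and chi-square comparisons).
    Also provides a reduced Michaelis-Menten reaction-network simulator
    solved to steady state with a stiff (Radau) integrator, mutation-profile
    perturbations (oncogene gain-of-function, tumor-suppressor
    loss-of-function, copy-number events), and a synthetic-cohort generator
    with known ground-truth labels for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
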