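Package: flowmig
Title: Agent-Based Simulation of Flow-Mediated Endothelial Migration and
    Vessel Bifurcation Stability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates endothelial cells migrating against blood flow in
    idealised bifurcated microvessel networks. Blood flow is solved as a
    one-dimensional Hagen-Poiseuille network problem in which each vessel
    segment's conductance scales with the fourth power of its cell number;
    cells advance one segment per time step against the local flow
    direction, so migration reshapes lumen diameters and thereby the flow
    and wall-shear-stress field that directs subsequent migration. At the
    flow-convergent bifurcation, where two upstream paths exist, cells
    choose a branch according to one of five decision rules, including a
    mechanistic stochastic rule that weights the branches' wall-shear-stress
    ratio against their cell-number ratio with a single parameter alpha.
    Provides ensemble machinery to sweep alpha over seed lists, detect
    branch regression and bifurcation loss, and summarise loss fractions,
    regression attribution, branch diameters, and branch-probability
    dynamics, together with a small command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
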