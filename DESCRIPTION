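Package: condcoop
Title: Conditional-Cooperation Norms and Community Membership Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulator and analysis toolkit for a threshold model of
    conditional cooperation coupled to a four-compartment model of community
    membership. Individuals cooperate when they believe enough others do;
    the population distribution of these thresholds (the norm-sensitivity
    distribution) drives a Granovetter-Schelling style dynamic. Outsiders
    join a community holding a rosy naive belief about its cooperation
    level, learn the truth at a gap-proportional rate, and leave when
    disillusioned. The package provides fixed-point and dilemma analysis
    of the basic threshold dynamic, stiff-capable integration of the
    community model, closed-form and numerically classified equilibria
    including a reproduction ratio for community growth, parameter scans
    with fold (saddle-node) detection, limit-cycle and bursting
    classification, and a configuration-driven command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
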