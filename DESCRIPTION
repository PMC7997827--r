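Package: mdoebox
Title: Model-Assisted Design of Experiments for Fed-Batch Bioprocesses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Couples a structured six-compartment kinetic model of yeast
    fed-batch cultivation and whole-cell biocatalysis with Monte-Carlo
    quantification of model-parameter uncertainty, k-means based planning
    of candidate experiments, Latin-Hypercube Monte-Carlo simulation of
    every candidate, and desirability-based ranking that recommends a
    small set of experiments to actually perform.  Includes a synthetic
    study generator so the whole workflow can be exercised without
    laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    lhs,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
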