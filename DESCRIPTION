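Package: flowbo
Title: Bayesian Self-Optimization of Telescoped Flow Syntheses on a Virtual Rig
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A virtual two-step telescoped flow reactor (packed-bed nitroarene
    hydrogenation followed by tubular amidation to acetaminophen) with catalyst
    deactivation and HPLC-like measurement noise, a closed-loop Bayesian
    optimizer built on a Matern-5/2 Gaussian-process surrogate with an adaptive
    expected-improvement acquisition function, Latin hypercube initialization,
    plateau termination, catalyst monitoring and anomaly rejection, and
    green-metrics reporting (process mass intensity, solvent-recycling
    scenarios, throughput) for comparing one-step-at-a-time against fully
    telescoped optimization campaigns.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
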