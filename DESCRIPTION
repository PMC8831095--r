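Package: nodeloc
Title: RSS-Based Trilateration for Automated Radio Telemetry Node Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Localization of radio-tagged animals from networks of fixed
    omnidirectional receivers (nodes) that log received signal strength (RSS).
    Fits the exponential decay relationship between RSS and distance by
    nonlinear least squares, inverts it to per-node distance estimates, and
    estimates planar locations by Gauss-Newton trilateration after selecting
    informative nodes with signal-strength or distance filters.  Includes a
    simulation framework for evaluating localization error across node
    network configurations (spacing, regularity, distance from the network
    edge), error summaries with cluster-bootstrap confidence intervals, and
    command-line entry points for fitting, localizing, simulating and
    evaluating.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
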