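Package: smlmsweep
Title: Density-Based Cluster Sweep Analysis for Two-Channel
    Single-Molecule Localization Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the spatial organization of bacterial
    surface protein complexes (cellulosomes) from two-channel
    single-molecule localization microscopy (PALM/STORM) coordinate
    tables.  Provides a from-scratch DBSCAN implementation with explicit
    core/border/noise semantics, a cluster-count profile obtained by
    sweeping the minimum-number-of-molecules parameter at a fixed epsilon
    radius with per-cell normalization, polygonal region-of-interest
    stratification, coordinate-based two-channel colocalization metrics,
    and a synthetic scene generator that emulates clustered emitters on
    cell surfaces and substrate particles, fluorophore blinking,
    localization error and background noise so that the whole pipeline
    can be validated against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
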