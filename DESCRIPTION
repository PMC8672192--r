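Package: netdegrade
Title: Data-Handling Error Models for Network Diffusion Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies how data-handling errors change the output of network
    diffusion models. Provides synthetic graph generators (Erdos-Renyi with a
    fixed edge count, Watts-Strogatz ring rewiring, Barabasi-Albert
    preferential attachment) and a SNAP-dialect edge-list loader; degradation
    models for batched random node/edge removal and entity-resolution-style
    node aggregation driven by skew-normal attributes, equal-width binning and
    shared-neighbour matching, with a matched random-merge baseline;
    discrete-time SIR and Threshold cascade engines; experiment orchestration
    with fully derived seeding, sigmoid transition-curve fitting and
    infection-probability calibration; and a command-line interface with
    shipped parameter presets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
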