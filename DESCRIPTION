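Package: trinet
Title: Three-State Asynchronous Logical Modeling of Signaling Networks
Version: 1.0.0
Authors@R:
    person("Jonas", "Ortega", email = "jortega@example.org",
           role = c("aut", "cre"))
Description: Qualitative dynamic modeling of signaling networks with
    three-state variables (below control, control, above control),
    signed regulatory interactions, per-interaction time delays, and
    asynchronous immediately-realized updates in randomized order.
    Ensembles of independent randomized runs emulate a heterogeneous
    cell population; in-silico perturbations (node knockouts, activity
    clamps, pathway deletions, delay edits) support hypothesis testing
    on network wiring. Ships a curated set of palmitate-induced
    ER-stress models of the PERK/PKR-eIF2alpha-ATF4 and CREB1 axes,
    with scenario files that regenerate the published simulation
    results.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
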