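Package: caruSim
Title: Stochastic and Deterministic Simulation of Cardiac Calcium Release Units
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Hybrid stochastic/deterministic model of calcium cycling in human
    ventricular myocytes. L-type calcium channels and ryanodine receptors are
    represented as Markov-chain channel populations advanced by binomial
    tau-leaping inside a whole-cell electrophysiology model; in the
    deterministic mode the same chains are integrated as mean-field occupancy
    equations. The package provides the pacing protocol, the per-beat
    sarcoplasmic-reticulum release statistic, phosphorylation and L-type
    channel regulation interventions, and channel-count sweep analyses that
    locate the transition from stochastic to deterministic-like calcium
    release.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
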