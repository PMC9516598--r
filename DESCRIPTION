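Package: cariesim
Title: Lifetime Markov Microsimulation of Caries Screening Strategies with
    Value-of-Information Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tooth-level Markov state-transition microsimulation of posterior
    proximal caries over a lifetime horizon, comparing dentist-only radiographic
    screening with dentist-plus-AI screening on bitewing radiographs. Propagates
    lesion-depth-specific diagnostic accuracy into treatment decisions and a
    restorative cascade (infiltration, restoration, crown, endodontic care,
    extraction, implant), aggregates discounted lifetime costs and tooth
    retention years, runs probabilistic sensitivity analysis with uniform and
    triangular parameter distributions, and computes cost-effectiveness outputs
    (ICER, cost-effectiveness plane, acceptability curves) and value of
    information (EVPI and per-parameter EVPPI) over a willingness-to-pay grid.
    Includes a calibrated synthetic parameter generator emulating accuracy
    learning curves over training-data fractions and low- and high-risk cohorts.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    jsonlite,
    ggplot2,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
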