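Package: mutlfoci
Title: Single-Cell Mutation Dynamics from Fluorescent Mismatch-Repair Foci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to turn tracked fluorescent MutL focus records from
    mother-machine time-lapse experiments into repair kinetics, detection-
    corrected focus and mutation rates, and tests of Poissonian versus
    bursty mutation dynamics. Includes a ground-truth lineage and focus
    simulator (Poisson error production, Bernoulli repair failure,
    interval-censored exponential repair lifetimes, discrete imaging with
    optional photobleaching, and an optional two-state telegraph process
    modulating repair failure), an interval-censored estimator of the mean
    short-focus lifetime, a bimodality-based short/long lifetime cutoff,
    exact Poisson and unconditional 2x2 inference for rates, and a
    Monte-Carlo-corrected goodness-of-fit test for inter-arrival times of
    focus onsets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
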