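Package: sisstop
Title: Race Modelling and EMG Analysis for Response-Selective Stopping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying response-selective stopping in the stop
    signal task, where a bimanual response must be partially cancelled:
    one hand stops, the other continues. Implements the
    simultaneously-inhibit-and-start (SIS) race model with ex-Gaussian
    runners and go/stop trigger failures, trial simulation, exact
    per-trial likelihoods, hierarchical Bayesian estimation by
    differential-evolution MCMC with BPIC model comparison and posterior
    contrasts, a censoring simulation explaining bias in EMG-based
    stopping-latency estimates, an EMG processing pipeline
    (single-threshold burst detection, RT-generating and partial-burst
    classification, CancelTime, envelope averaging), staircased task
    schedules, and a synthetic-data generator producing behaviour and raw
    EMG with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
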