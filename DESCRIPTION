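Package: engramsim
Title: Rate-Network Simulation of Memory Engram Allocation and Linking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Simulates a rate-based recurrent neural network in which Hebbian
    synaptic plasticity and activity-dependent intrinsic excitability jointly
    control which neurons are allocated to memory engrams. Contextual
    fear-conditioning protocols are expressed as stimulation schedules
    (training sessions, recall probes, excitability and inhibition
    manipulations) and integrated with a multi-resolution explicit Euler
    scheme. Read-outs include engram membership, a behavioural memory-strength
    observer, engram overlap, and trial exclusion on runaway firing rates.
    Named multi-trial experiments reproduce engram formation, pattern
    completion from partial cues, temporally graded engram overlap, and
    memory linking, with tidy per-trial and aggregate results.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
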