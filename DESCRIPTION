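Package: snailwave
Title: TGF-beta/SMAD/GLI1 Crosstalk Models of Two-Wave SNAIL1 Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nested ordinary-differential-equation models of the TGF-beta
    signalling network that relays from SMAD to GLI1 and converges on the
    transcription factor SNAIL1, together with the tools needed to study it:
    a multi-start Metropolis Monte Carlo calibration engine driven by
    fold-change constraint tables, in-silico inhibitor and pulse-duration
    experiments, a generic boosted positive-feedback motif analysis of
    response times, coarse-grained temporally ordered state-space (TOSS)
    encoding of trajectories, and seeded generators of immunofluorescence-like
    single-cell populations and qPCR-like replicate fold changes. Trajectories,
    parameter sets and constraint tables are exchanged as tibbles, CSV and
    JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    lhs,
    mclust,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
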