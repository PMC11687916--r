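Package: mmchain
Title: Momentum Chain Modelling for Point-by-Point Tennis Data
Version: 0.1.0
Authors@R:
    person("Momentum", "Maintainers", email = "maintainers@mmchain.dev",
           role = c("aut", "cre"))
Description: Quantifies per-point psychological momentum of tennis players
    from point-by-point match records using a difference-equation model with
    an exponential forgetting coefficient and linearly weighted gain/loss
    events (winning serves, winning shots, three-point runs, double faults,
    unforced errors, three-point slumps). Includes readers and writers for
    the public Grand Slam point-by-point CSV dialect, event-flag extraction
    with streak and break-point detection, event-level statistics
    (contingency chi-square tests, court-type variance summaries, event
    correlation matrices, score time series), match-winner prediction from
    the momentum differential, and a full tennis scoring state machine with
    a stochastic point simulator that provides ground-truth annotations for
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
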