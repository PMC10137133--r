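Package: nccborrow
Title: Borrowing Non-Concurrent Control Observation Time in Platform Trials
Version: 0.1.0
Authors@R:
    person("Platform Trials", "Methods Group", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for time-to-event analysis in platform trials where a new
    experimental arm joins an ongoing study. Control patients recruited before
    the new arm's entry (non-concurrent controls, NCC) contribute only their
    concurrent observation time to the comparison, via left truncation of the
    non-concurrent period. Provides a staggered-accrual piecewise-exponential
    trial simulator, delayed-entry Kaplan-Meier and Cox partial-likelihood
    estimation with Wald inference, a two-sample log-rank test with late-entry
    risk sets, Monte Carlo operating characteristics for competing control
    strategies, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
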