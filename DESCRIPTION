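Package: ph2select
Title: Bayesian Treatment Selection Designs for Two-Arm Randomised Phase II
    Trials with a Binary Endpoint
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and analysis of two-arm randomised phase II
    ("pick-the-winner") selection trials with a binary endpoint in a
    Bayesian framework.  Conjugate Beta-binomial updating yields the
    posterior probability of correct selection, the posterior probability
    of an ambiguous outcome, and the combined decision criterion
    lambda* = PCorr* + rho * PAmb*, with a threshold rule for advancing the
    better-performing arm.  Two sample-size determination algorithms are
    provided: a deterministic search that plugs in expected responder
    counts, and a more stable simulation-based search that averages
    lambda* over binomial sampling of the counts (with an exact
    enumeration backend).  Operating characteristics (probability of
    correct selection and of deferral to secondary factors) are estimated
    by seeded Monte Carlo or computed exactly by enumeration.  The exact
    binomial Sargent-Goldberg frequentist selection design is included as
    a comparator, together with report generation and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
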