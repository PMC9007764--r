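Package: timemotion
Title: Time-Motion Analysis of Multidimensional Clinical Work Observation Logs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing continuous direct-observation (time-motion)
    event logs of clinical work, as collected with multidimensional
    work-observation methods (what/where/how/who task dimensions, overlapping
    tasks, linked interruptions).  Provides exact interval algebra for
    overlap-aware time-budget estimation with configurable denominators,
    interruption and multitasking statistics, cluster-bootstrap confidence
    intervals and Monte Carlo permutation tests for group contrasts,
    chance-adjusted inter-rater agreement on one-second windows (the
    multivariate iota score with Cohen's kappa as its univariate special
    case), and a synthetic session generator with known ground truth for
    validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
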