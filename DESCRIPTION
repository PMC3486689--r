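Package: shiftselect
Title: Bayesian Model Selection in a Visuomotor Shift Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses a two-part visuomotor model-selection
    experiment in which a lateral cursor shift is drawn from one of two
    candidate shift distributions and observers report the generating model.
    Implements five competing accounts of probe-trial choice behaviour: an
    ideal observer comparing marginal likelihoods via Bayes factors with a
    softmax choice rule, Bayesian policy inference that superposes fitted
    standard-trial response curves under the shift posterior, and three
    shift heuristics (average, biggest, halfway). Includes a synthetic-subject
    simulator of the full trial schedule, psychometric-curve fitting by
    least squares, negative log-likelihood model comparison with model- and
    parameter-recovery studies, and the associated exact significance tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
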