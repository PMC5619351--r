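Package: clockdraw
Title: Algorithmic Scoring and Reliability Analysis for the Clock Drawing Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic scoring of the Clock Drawing Test (CDT) from a
    17-item binary feature checklist, using a decision algorithm adapted from
    the 10-point Sunderland scale. Provides exhaustive enumeration of all
    checklist profiles and score preimages, inter-rater agreement statistics
    (percent agreement, Cohen's kappa, linear and quadratic weighted kappa,
    Fleiss' kappa, Pearson correlation), a synthetic-cohort generator that
    calibrates a maximum-entropy score distribution to published summary
    statistics and inverts the scoring algorithm by preimage sampling, a
    multi-rater noise simulator, and CSV readers/writers with a command-line
    interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
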