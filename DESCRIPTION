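Package: vwmtrain
Title: Mixture-Model Analysis of Visual Working Memory Training Studies
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing continuous-reproduction and change-detection
    measures of visual working memory in pre/post training designs. Implements
    the two-component standard mixture model (von Mises + uniform) for recall
    errors with maximum-likelihood fitting, yielding capacity (quantity) and
    precision (quality) estimates; Pashler's k for whole-display change
    detection; robust trimmed-mean inference (Yuen t-tests, Algina-Keselman-
    Penfield effect sizes), mixed and repeated-measures ANOVAs with generalized
    and partial eta squared; default Bayes factors (JZS t-test, Gunel-Dickey
    contingency tables, BIC approximations for ANOVA effects); a trial-level
    study simulator; and an end-to-end analysis pipeline with exclusion rules
    and response-density comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
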