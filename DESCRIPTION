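Package: consensim
Title: Simulation and Analysis of Consensus-Method Trials for Guideline
    Development
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate and analyze randomized comparisons of
    consensus methods for clinical practice guideline development, such as
    a game-based (human computation) protocol versus an informal
    face-to-face meeting. Provides a seeded opinion-dynamics simulator of
    the multi-round trial design, the signed normalized group evidence
    score for GRADE-graded answer options, single-item multirater
    agreement kappa with free- and fixed-marginal chance models, within-
    and between-group Cohen's d on round-wise changes, exact small-sample
    Wilcoxon signed-rank and Mann-Whitney U tests, thematic-coding
    quantification with inter-coder Cohen's kappa, and an end-to-end
    pipeline with Monte-Carlo power and calibration analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
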