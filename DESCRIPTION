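Package: dyadgame
Title: Linear-Quadratic Dynamic Game Models of Jointly Controlled Reaching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to model, simulate and analyse visuomotor feedback
    responses of human pairs who jointly control a shared cursor. Two
    hands are modelled as point-mass controllers in a finite-horizon
    linear-quadratic dynamic game with delayed, noisy sensory feedback
    and Kalman state estimation. Nash-equilibrium or decoupled feedback
    gains are solved under four partner-representation / joint-cost
    policy hypotheses, and force-channel probe trials with cursor or
    target jumps are simulated to predict involuntary visuomotor
    feedback responses. The package also provides the full empirical
    analysis pipeline: Butterworth filtering, visual-delay alignment,
    left/right force differencing, epoch averaging, a synthetic paired
    dataset generator, repeated-measures ANOVA, recentered paired
    bootstrap tests with Holm-Bonferroni correction, and common-language
    effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
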