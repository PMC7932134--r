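Package: vibropalp
Title: Objective Metrics and Simulation for Vibrotactile Palpation Skill Assessment
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying vascular palpation skill from fingertip
    motion-capture trials on a vibrotactile simulator. Computes five objective
    per-trial metrics (accuracy, duration, total path length, ratio of correct
    movement, error rate), fits random-intercept linear mixed models and a
    logistic generalized linear mixed model of haptic-factor effects with odds
    ratios, and generates calibrated synthetic palpation studies at both
    metric and trajectory fidelity so the full pipeline can be exercised and
    validated without access to raw study data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
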