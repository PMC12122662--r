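Package: copdcea
Title: Trial- and Model-Based Cost-Effectiveness Analysis for a COPD
    Early-Warning Intervention
Version: 0.1.0
Authors@R:
    person("Predict", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for the economic evaluation of a digital early-warning
    self-management system for chronic obstructive pulmonary disease (COPD)
    against usual care, from a UK NHS perspective.  Implements a within-trial
    cost-utility and cost-effectiveness analysis (QALYs by the area-under-the-
    curve method, chained multiple imputation, covariate-adjusted incremental
    costs and effects with non-parametric bootstrapping, cost-effectiveness
    acceptability curves), a five-year Markov cohort model over GOLD stages
    A-D with post-discharge tunnel states and death on admission, annually
    decaying treatment effects, probabilistic sensitivity analysis, and
    expected value of (partial) perfect information.  A synthetic trial-data
    generator with closed-form ground truth supports recovery testing, and a
    patient-level microsimulation provides an independent oracle for the
    cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    mgcv,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
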