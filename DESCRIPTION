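Package: medgf
Title: Mediational G-Formula for Obesity Trajectories, Inactivity and
    Physical Functioning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Longitudinal causal mediation analysis for time-varying
    exposures, mediators and confounders. Implements the parametric
    mediational g-formula with randomized-interventional-analogue natural
    direct and indirect effects (rTE, rNDE, rNIE) of life-course obesity
    trajectories on later poor physical functioning, mediated by
    time-varying physical inactivity. Counterfactual risks are computed by
    Monte Carlo g-computation from wave-sequential logistic models, with
    bootstrap confidence intervals. Includes a seeded synthetic cohort
    generator emulating the wave structure and marginal prevalences of two
    British birth cohorts, an exact enumeration oracle for all-binary
    structural models, derivation utilities (obesity flags, onset-based
    trajectory classes, gender-specific centile dichotomization of a
    functioning score), adjusted odds-ratio summaries, and a config-driven
    pipeline.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
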