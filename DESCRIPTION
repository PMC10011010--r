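Package: mbebfda
Title: Functional Data Analysis of Multiple Brief Exercise Bout Tests
Version: 0.1.0
Authors@R:
    person("MBEB", "FDA Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing cardiopulmonary signals (heart rate,
    respiratory rate, oxygen uptake, carbon dioxide output) recorded
    during multiple-brief-exercise-bout (MBEB) protocols in children and
    adolescents, and for predicting task failure from the first four
    bouts.  Provides a synthetic cohort generator with first-order
    on/off exponential kinetics over a square-wave work-rate schedule,
    second-by-second interpolation and quality control, penalized
    B-spline smoothing with a harmonic-acceleration roughness penalty
    and generalized cross-validation, continuous curve registration with
    a phase/amplitude variance decomposition, functional permutation
    t-tests and bootstrap functional ANOVA, and supervised curve
    discrimination through functional principal component scores with a
    generalized spectral additive model and six baseline classifiers
    under stratified cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    mgcv,
    splines,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
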