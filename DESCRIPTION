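Package: rarfosr
Title: Rest-Activity Rhythm Analysis with Function-on-Scalar Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of wrist-actigraphy rest/activity rhythms (RARs) in
    two-group cohort studies. Converts epoch-level activity counts into
    valid-day-filtered 24-hour mean and across-day-SD profiles of
    log-transformed activity, computes standard one-component cosinor metrics
    (MESOR, amplitude, acrophase), nonparametric circadian statistics
    (interdaily stability, intradaily variability, relative amplitude with
    M10/L5), and actigraphic sleep parameters from scored rest intervals.
    The core is a function-on-scalar regression (FOSR) engine: penalized
    generalized least squares on a spline basis with GCV-selected smoothing,
    pointwise and simultaneous confidence bands, a permutation global F-test,
    and extraction of clock-time windows where a covariate effect is
    significant. A synthetic two-group cohort generator with closed-form
    ground truth supports power and coverage studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
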