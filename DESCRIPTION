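Package: cardioauto
Title: Cardiovascular Autonomic Analysis of Telemetered Rodent Beat Series
Version: 0.1.0
Authors@R: person("Repo", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of beat-annotated rodent telemetry:
    ectopic-interval filtering, time- and frequency-domain heart rate
    variability per 5-minute segment, spontaneous baroreflex sensitivity by
    the sequence method, rule-based classification of atrial premature beats
    and atrioventricular conduction block, ECG morphology and hemodynamic
    features (QT rate correction, ST metrics, dP/dt max), whole-body
    plethysmography respiratory timing with a pre-arrhythmia ventilatory
    disturbance screen, and a delta-from-baseline inference layer using
    linear mixed models, Poisson generalized estimating equations, and
    simple or group-adjusted correlations. Includes a synthetic telemetry
    generator with a complete ground-truth log for validating every
    estimator in the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nlme
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
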