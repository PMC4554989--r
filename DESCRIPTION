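Package: springdamp
Title: Spring-Damper Modelling of Animal Responses to Acute Perturbations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies resistance and recovery of animals facing an acute
    environmental challenge with a Kelvin-Voigt (spring and damper in
    parallel) model. Simulates response trajectories by closed form and by
    numerical integration of the piecewise regime-switching system, fits
    stiffness (K) and resistance (C) to sparse longitudinal measures by
    multi-start least squares, scores fits with the modelling efficiency
    statistic, derives the recovery decay constant T = C/K, the asymptotic
    deformation and the peak response, runs one-at-a-time sensitivity sweeps,
    generates synthetic cohorts emulating a confinement-challenge study in
    isogenic rainbow trout lines, and aggregates per-individual fits into
    group-level summaries, outlier exclusion by Tukey fences, line contrasts
    and between-parameter correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
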