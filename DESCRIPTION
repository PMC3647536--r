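Package: msdoublewell
Title: Stochastic Double-Well Modelling of Relapsing-Remitting Disease Course
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the relapsing-remitting course of multiple sclerosis as
    noise-driven switching between the two wells of an asymmetric quartic
    potential. Provides the closed-form geometry of the double well
    (stationary states, barriers, saddle-node bifurcation boundary),
    Euler-Maruyama integration of the overdamped Langevin equation with
    hysteresis-based residence-time extraction, Kramers-type mean exit-time
    algebra, a log-ratio estimator of the barrier asymmetry from clinical
    relapse/remission durations with inversion for the asymmetry parameter,
    a synthetic patient-cohort generator with exponentially distributed
    episode durations on a weekly grid, and a per-patient and cohort
    inference pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
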