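Package: VNSens
Title: Global Sensitivity Analysis of Cardiac-Synchronized Vagus Nerve
    Stimulation Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks the burst parameters of cardiac-synchronized vagus nerve
    stimulation (current amplitude, number of pulses, pulse width, interpulse
    period, onset delay) by their acute chronotropic, dromotropic and inotropic
    effects. Provides an optimized maximin Latin hypercube experimental design,
    beat-level effect quantification with bradycardia/adverse-event exclusion
    rules, per-subject Gaussian-process (kriging) surrogates with covariance
    family selection by repeated cross-validation, Monte-Carlo Sobol variance
    decomposition (main, total, second- and third-order indices), and bootstrap
    inter-subject summaries, together with a synthetic cohort generator that
    emulates the statistical structure of the sheep experiments so the whole
    pipeline is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    lhs,
    boot,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
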