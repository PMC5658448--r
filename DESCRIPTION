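Package: kinsig
Title: From Receptor Binding Kinetics to Signal Transduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulation and analysis of competitive receptor binding
    kinetics coupled to transient functional readouts, modelled on real-time
    cAMP (GloSensor-type) and impedance (xCELLigence-type) assays at the
    neurokinin-1 receptor. Provides a mass-action ODE simulator for up to three
    competing ligands under piecewise-constant addition schedules with
    Motulsky-Mahan and Gaddum closed-form oracles, an operational-model style
    occupancy-to-response transduction stage with desensitization, protocol
    builders for concentration-response, IC50-at-EC80, dual-point competition
    association and single time-course experiments, and the corresponding
    analysis procedures: the kinetic rate index (KRI), peak analysis with
    variable-slope concentration-response fitting and normalization,
    IC50 fitting, the 8-minute onset-of-activation statistic, one-way ANOVA
    with Dunnett's post-test, and surmountability classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    multcomp,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
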