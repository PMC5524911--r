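Package: cardiolpm
Title: Personalized Lumped-Parameter Modelling of the Left Heart and
    Systemic Circulation
Version: 0.1.0
Authors@R:
    person("cardiolpm", "developers", email = "cardiolpm@example.org",
           role = c("aut", "cre"))
Description: Simulation and subject-specific personalization of a
    lumped-parameter (0D) model of the pulmonary venous system, the left
    heart, and the systemic arterial circulation. Heart chambers follow a
    time-varying elastance ("double-Hill") description, valves are
    diode-gated resistance/inertance elements with an energy-loss
    (pressure recovery) treatment of the aortic valve, aortic segments
    are viscoelastic RLC segments, and arterial outlets terminate in
    three-element Windkessel models. The package estimates model
    parameters from non-invasive measurements (five volumetric flow
    waveforms, brachial cuff pressures, end-systolic volume, and aortic
    valve geometry) in two stages: closed-form initialization from
    clinical indices followed by bounded Levenberg-Marquardt least
    squares against the measured flow waveforms. Profile-likelihood
    machinery classifies parameters as identifiable, practically
    non-identifiable, or structurally non-identifiable. A virtual-subject
    generator produces synthetic measurement bundles from known
    ground-truth parameters so the full pipeline can be validated end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
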