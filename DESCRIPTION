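Package: mdpkpd
Title: Microdialysis Pharmacokinetic-Pharmacodynamic Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for brain-microdialysis drug studies:
    dual-range LC-MS calibration with limit-of-detection and
    quality-control statistics, in-vitro probe recovery estimation and
    concentration correction, non-compartmental pharmacokinetic analysis
    of interval-averaged dialysate profiles, one- and two-compartment
    oral-absorption model fitting with AIC/BIC/CV model selection,
    sigmoid Emax/Imax pharmacodynamic models, effect-compartment (ke0)
    PK-PD linking, and signed-area quantification of
    concentration-effect hysteresis loops. Includes a synthetic-data
    generator that emulates interval-averaged microdialysis sampling of
    compartmental profiles with probe-recovery attenuation and delayed
    neurotransmitter responses, providing ground truth for validating
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
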