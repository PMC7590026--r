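Package: mnpheat
Title: Magnetic Nanoparticle Hyperthermia Heating Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of magnetic fluid hyperthermia in
    superparamagnetic zinc-substituted magnetite nanoparticles.
    Fits Langevin/log-normal magnetization curves to extract magnetic
    diameters, computes field-dependent Neel and Brown relaxation times
    and relaxation-regime maps, evaluates linear-response and
    Langevin-saturation models of the specific absorption rate (SAR),
    extracts SAR from calorimetric heating curves by the initial-slope
    method, and fits SAR versus field-amplitude curves under the
    constrained saturation model across dispersion conditions.
    Includes deterministic synthetic-data generators with known ground
    truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
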