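Package: agecsf
Title: Age-Dependent Analytical Contrast Sensitivity Functions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analytical model of the human spatial contrast sensitivity
    function (CSF) in which the optical and physiological components of
    Barten's signal-to-noise CSF model -- pupil diameter, optical
    modulation transfer function, retinal illuminance, photon and neural
    noise, and retinal cone and ganglion cell densities -- are explicit
    functions of observer age. Provides forward prediction of spatial and
    spatiotemporal CSFs for photopic viewing conditions, fitted analytical
    age curves for the model's four free parameters, a deterministic
    grid-search engine for estimating those parameters from tabulated CSF
    measurements, model-comparison reports, a synthetic CSF data
    generator, CSV/JSON input and output, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
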