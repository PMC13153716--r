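Package: usfdyn
Title: Dynamic Forward Models for Ultrasound-Switchable Fluorescence Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulator for ultrasound-switchable fluorescence (USF)
    deep-tissue imaging. Couples an analytic focused-ultrasound pressure
    field with a Pennes bioheat finite-difference solver, a
    temperature-gated fluorescence quantum-yield model (complementary
    error function switching), and semi-infinite photon diffusion with
    extrapolated-zero-boundary image sources, to produce dynamic USF
    signals and velocities, surface point-spread maps, time-dependent
    sensitivity (weight) matrices, and closed-form resolution analytics
    for two-point temporal separability.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
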