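Package: ospra
Title: Simulation and Calibration Chain for a Miniature CMOS Spectroradiometer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hardware-free implementation of the measurement chain of a
    low-cost, high-sensitivity spectroradiometer built around a 288-photosite
    CMOS line sensor with a 10-bit analogue-to-digital converter and a
    shutter/cosine-corrector head. Provides a generative sensor simulator
    (dark current, shot and read noise, count nonlinearity, saturation,
    stray-light pedestal), exposure planning with automatic integration-time
    selection and scan averaging, dark-frame subtraction, a two-coefficient
    count-linearisation model fitted by nonlinear least squares, relative and
    absolute spectral-sensitivity calibration, cosine-corrector angular
    response evaluation, conversion of counts to spectral radiance and
    irradiance, low-light dark-offset correction, CIE-weighted luminance and
    illuminance, and plain-CSV persistence of calibration and measurement
    records with lossless re-calibration from stored raw counts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
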