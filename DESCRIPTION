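Package: rrvideo
Title: Non-Contact Respiratory Rate Estimation from Thermal Video by
    Phase-Based Motion Magnification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Measures the respiratory rate of caged broiler chickens from
    infrared thermal video without contact. The pipeline screens clips for
    quiet (motionless) 10-second windows using dense optical flow, decomposes
    region-of-interest video with a complex steerable pyramid, band-pass
    filters and linearly amplifies the local spatial phase (phase-based video
    magnification), and reads the respiratory rate off the dominant peak of
    the FFT magnitude spectrum inside the physiological band 0.3-3.0 Hz.
    Includes a synthetic thermal-video simulator with known ground-truth
    breathing frequency, growth-stage and heat-stress presets, and the full
    agreement-metric suite (MAE, MAPE, RMSE, identity-line R-squared, Pearson
    r, Bland-Altman limits of agreement, age-trend regression) used to
    validate such measurements against manual counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
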