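Package: venose
Title: Virtual Electronic Nose Analysis of Temperature-Cycled Gas Sensor Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and chemometric analysis of a single gas sensor
    operated in temperature-cycled (dynamic) mode as a virtual sensor
    array. Provides a phenomenological simulator for a SiC field-effect
    transistor sensor cycled over five temperature plateaus and exposed
    to short-chain oxygenated volatile organic compounds; cycle
    segmentation, Savitzky-Golay smoothing, per-cycle auto-scaling and
    virtual-sensor construction; a 299-dimensional windowed feature
    catalog (means, slopes, FFT magnitudes, integral, lifting);
    sequential forward feature selection with cross-validated criteria;
    and the evaluation heads used in electronic-nose studies: linear
    discriminant projections, cross-validated support vector machine
    classification of gas identity and concentration, and partial least
    squares regression for concentration calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    signal,
    e1071,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
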