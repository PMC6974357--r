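Package: farredo2
Title: Mapping Far-Red Cyanobacterial Photosynthesis from Hyperspectral and
    Ratiometric Oxygen Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for locating chlorophyll f-containing
    cyanobacteria in rock cross-sections from hyperspectral reflectance
    image cubes and quantifying their near-infrared-driven oxygenic
    photosynthesis from ratiometric luminescent O2-optode image time
    series. Pigment absorption bands (chlorophyll a at 670-680 nm,
    chlorophyll f at 718-722 nm) are mapped by fourth-derivative
    spectroscopy of calibrated reflectance spectra; O2 optode RGB frames
    are converted to percent air saturation via an exponential
    delta-ratio calibration; apparent dark respiration, net and gross
    photosynthesis images are derived from light-dark shifts, summarised
    over regions of interest, and scaled to areal productivity. A
    synthetic-scene generator provides hyperspectral cubes and optode
    time series with closed-form ground truth so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    minpack.lm,
    jsonlite,
    tiff,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
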