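Package: cropsight
Title: Fertile-Land Discovery and Crop Suitability from Satellite-Style Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A deterministic toolkit for finding cultivable green land in
    satellite-style RGB imagery and recommending crops for it. Implements
    pan-sharpening of a low-resolution multispectral image with a
    high-resolution panchromatic band (high-pass-filter fusion and the Brovey
    ratio transform), HSV hue-window segmentation of vegetated area with
    acreage estimation from a map scale, a rule-based crop recommendation
    engine driven by environmental attributes (temperature, humidity, wind,
    precipitation, UV index, soil moisture, terrain), and an evaluation
    harness producing per-crop precision/recall/F1 classification reports and
    confusion matrices against a dominant-crop reference. Ships seeded
    synthetic-scene and attribute generators so the whole pipeline is testable
    offline with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
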