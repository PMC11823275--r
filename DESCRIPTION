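Package: hyperskin
Title: Hyperspectral Facial Skin Reflectance and Colorimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing hyperspectral images of human facial skin:
    recovery of spectral reflectance from raw hyperspectral counts using an
    in-scene Munsell N7 gray reference and an illuminant spatial-uniformity
    map, per-pixel CIELAB colorimetry under CIE D65, spectral and chromatic
    difference metrics (RMSE, delta E, NRMSE goodness of fit, S-CIELAB),
    discernible-color volume estimation by unit-cube counting, nine-position
    facial region-of-interest statistics with left-right and skin-tone group
    comparisons, and cross-device comparison against telespectroradiometer and
    contact spectrophotometer readings. Includes a melanin-hemoglobin
    synthetic face-cube generator with known ground truth so the full pipeline
    is testable end to end, plus ENVI cube and CSV spectrum input/output.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
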