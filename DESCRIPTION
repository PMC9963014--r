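Package: rgbfvc
Title: Fractional Vegetation Cover from RGB Imagery via the Dimidiate Pixel Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts fractional vegetation cover (FVC) from plain RGB
    (visible-band) imagery. Seven visible-band vegetation indices (EXG,
    GRVI, EXGR, NGBDI, CIVE, RGBVI, VDVI) are fed through the dimidiate
    (pixel-dichotomy) model, with pure-soil and pure-vegetation endpoints
    estimated as percentile cuts of the index histogram. Includes
    accuracy-evaluation metrics (reference FVC from classified maps,
    extraction error, confusion matrix, overall accuracy, Cohen's kappa),
    cover-grade mapping, multi-date change analysis, and a seeded
    synthetic-scene generator with ground truth for end-to-end testing.
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
    jpeg,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
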