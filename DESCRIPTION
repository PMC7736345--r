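Package: nirgist
Title: Per-Pixel Tissue Classification of Submucosal Gastric Tumors from
    Near-Infrared Hyperspectral Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Tools for distinguishing submucosal gastrointestinal stromal
    tumor (GIST) tissue from normal gastric tissue, pixel by pixel, in
    near-infrared hyperspectral images (1000-2350 nm). Implements white/dark
    reflectance calibration and ENVI cube input/output, spectral band
    selection and highlight/shadow masking, standard normal variate (SNV)
    normalization, a soft-margin support vector machine with RBF kernel and
    median-heuristic bandwidth solved by dual decomposition,
    leave-one-specimen-out cross-validation, boundary-exclusion confusion
    accounting with specificity/sensitivity/accuracy reporting, and overlay
    rendering. A seeded synthetic-specimen generator with layered
    Beer-Lambert absorbance mixing makes the whole pipeline testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    grDevices,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils
Suggests:
    e1071,
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
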