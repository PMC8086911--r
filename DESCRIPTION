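Package: elfr
Title: Environmental Light Field Analysis from Calibrated Fisheye Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts bracketed 180-degree fisheye exposures from a
    radiometrically calibrated camera into absolute photon radiance
    statistics as a function of elevation angle. Implements the
    environmental light field (ELF) workflow: linear sensor counts to
    photon radiance (log10 'lit' units), equisolid-to-equirectangular
    remapping, high-dynamic-range merging of exposure brackets, robust
    per-elevation-bin statistics (median and 50%/95% contrast-spans for
    red, green, blue and white bands), geometric-mean aggregation of
    scenes into environment descriptions, the standard four-panel chart,
    and a synthetic-scene generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    patchwork,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    zip
Suggests:
    optparse,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
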