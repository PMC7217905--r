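Package: coralba
Title: Coral Skeletal Ba/Ca Sediment-Load Proxy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for reconstructing terrigenous sediment-load histories from
    massive coral cores. Builds tie-point age models from skeletal Sr/Ca
    anchored to instrumental sea-surface temperature, resamples depth profiles
    to a monthly grid, decomposes Ba/Ca records into multidecadal (Gaussian
    low-pass) and sub-biennial (notch) components, detects event-scale
    high-peaks against the mean seasonal cycle and matches them to documented
    flood catalogues, locates multidecadal trend shifts with a SiZer
    (significant zero crossings of derivatives) scan, computes annual
    extension, density and calcification rates, and fits barium-salinity
    endmember mixing lines to water samples. A forward simulator generates
    virtual coral cores with known chronology, trend shifts and spike events
    so every stage can be validated against truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
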