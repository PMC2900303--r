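Package: caltrace
Title: Ratiometric Calcium Imaging Analysis of Embryonic Ca2+ Transients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dual-excitation (Fura-2, 340/380 nm)
    ratiometric calcium imaging of developing embryos. Computes masked
    pixel-wise ratio stacks from paired fluorescence image stacks, detects
    localized short-lived Ca2+ release events (transients) by a subtractive
    frame-difference algorithm with robust noise thresholding, classifies
    transient versus sustained release by a 30-second persistence rule,
    accumulates per-session composite activity maps, contrasts activity
    inside and outside a lineage-tracer region of interest, converts event
    tables into transients-per-hour over developmental-stage windows, and
    performs the associated group statistics (one-way ANOVA with Tukey HSD,
    two-tailed Fisher's exact). A synthetic dual-wavelength movie generator
    with ground-truth event logs supports validation and benchmarking.
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
    grDevices,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    png,
    utils,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
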