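Package: mcsquant
Title: Quantitative Analysis of ER-Plasma Membrane Contact Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Morphometry of cortical-ER/plasma-membrane contact sites from
    traced membrane pairs (gap distance, cortical-ER length, cylindric cleft
    volume, gap-versus-length plateau estimation), ratiometric Fura-2
    calcium-imaging kinetics (R/R0 traces, derivative-guided slope extraction
    for store-operated entry, extrusion and Mn2+-quench rates, peak
    amplitudes), and TIRF puncta quantification (segmentation, coverage,
    line profiles). Includes seeded synthetic-data generators for every
    input type so the whole pipeline is testable without raw microscopy
    data, plus group statistics (one-way ANOVA with Tukey or Dunnett
    post-hoc tests) and a reproducible pipeline driver.
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
    multcomp,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
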