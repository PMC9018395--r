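Package: mompscreen
Title: Image-Based siRNA Screen Analysis for Heterogeneous Mitochondrial
    Outer Membrane Permeabilization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing high-content imaging screens of apoptotic
    mitochondrial outer membrane permeabilization (MOMP) heterogeneity.
    Implements per-cell phenotyping of fluorescent BAX and OMI reporter
    puncta (nuclear segmentation, cell-region assignment, granule
    detection), per-well phenotype summaries, plate quality control via
    the Z-prime factor, rank-tail hit calling across triplicate plates,
    secondary-screen siRNA concordance filtering, and clonogenic-survival
    quantification from stained colony images (covered-area measurement,
    survival normalisation, two-way ANOVA). A seeded synthetic-data
    generator produces multi-channel field images with per-cell ground
    truth, imageless screen score tables, and colony-well images for
    validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    tiff,
    png,
    EBImage,
    car
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
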