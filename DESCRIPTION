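Package: fleacyto
Title: Single-Cell Phosphatase Activity by Fluorescence Image Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies extracellular phosphatase activity of individual algal
    cells from dual-channel epifluorescence micrographs (FLEA assay, ELF97
    labeling). Provides a synthetic field-image generator with known per-cell
    ground truth, chlorophyll-based cell segmentation, per-cell fluorescence
    quantification with background subtraction and exposure normalization,
    prolate-spheroid cell volume estimation, specific growth rates from
    dilution-punctuated semi-continuous culture series, geometric-bin activity
    frequency distributions, and factorial treatment comparisons (three-way
    ANOVA with Tukey HSD).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    tiff,
    EBImage,
    emmeans,
    multcomp,
    generics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
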