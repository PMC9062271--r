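Package: woodyAGB
Title: Woody Aboveground Biomass and Disturbance Losses in Savanna Ecosystems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based estimation of standing woody aboveground biomass
    (AGB) and disturbance-attributed AGB losses in savanna and dry woodland
    inventories. Implements growth-class-specific allometric workflows that
    combine a canopy-based model for shrub-like individuals with a stem-based
    model for tree-like individuals, locally calibrated proxy-reconstruction
    regressions (height from DBH, DBH from basal circumference, basal
    circumference from an alternative stem reading), specific wood density
    computation from core and stem-piece samples, per-agent damage
    partitioning with dead-stem (topkill) accounting, and nested-plot
    upscaling to stand level. Includes a synthetic inventory generator with
    known ground truth for end-to-end validation, and a thin command-line
    pipeline.
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
    readr,
    rlang,
    stats,
    jsonlite,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    readxl,
    optparse,
    withr
Config/testthat/edition: 3
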