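Package: qlcis
Title: Quantitative Live-Cell Imaging of Secretion Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis stack for time-lapse fluorescence immunospot assays on
    nanoliter-well arrays (quantitative live-cell imaging of secretion, qLCI-S).
    Converts per-well cumulative secretion signals into per-interval release
    estimates by inverting empirical antibody staining kinetics, compensates
    IL-13 cross-reaction with captured IL-5, calls and classifies secretory
    phenotypes with robust MAD-based thresholds, localizes secretion relative
    to tracked cells via 2D Gaussian fits, validates total-internal-reflection
    optics configurations, and ships a synthetic nanowell-experiment generator
    so the whole pipeline can be exercised without microscope data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
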