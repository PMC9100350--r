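Package: skincap
Title: Skin Capacitive Image and Trans-Epidermal Water Loss Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing capacitive skin-hydration images together
    with trans-epidermal water loss (TEWL) measurements. Implements six
    template-matching scoring functions (squared differences, cross
    correlation and correlation coefficient, each plain and normalised) for
    relocating a region of interest across repeated captures of the same
    skin site, permittivity-scale hydration statistics and histograms,
    repeat-measurement summaries (mean, standard deviation, coefficient of
    variation, before/after changes), and a principal-component-analysis
    image distance for ranking skin sites by similarity. A synthetic
    generator emulates skin micro-relief texture, hydration-dependent
    brightness, inter-capture translation jitter and instrument noise so
    the full pipeline can be exercised on ground-truthed data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
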