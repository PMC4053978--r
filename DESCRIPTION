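Package: cnscreen
Title: Genome-Wide Fitness Profiling Across Carbon-by-Nitrogen Nutrient Grids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for colony-array fitness screens of a yeast
    deletion collection across a combinatorial grid of carbon and nitrogen
    sources. Converts colony-area time courses into growth rates, builds a
    glucose:ammonium reference condition from replicate plates, performs
    LOWESS plate normalization and spatial bias correction, computes
    condition-specific modified z-scores with Benjamini-Hochberg FDR hit
    thresholds from a wild-type replicate null, fits a multiplicative
    (log-linear) wild-type carbon-by-nitrogen interaction model, decomposes
    sensitivity profiles into per-nutrient-source signatures with a
    fixed-coefficient non-negative matrix factorization, and supports
    profile-similarity function prediction, condition clustering,
    set-overlap and sign tests. Includes a synthetic screen generator with
    known ground truth for end-to-end validation.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
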