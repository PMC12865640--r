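Package: spaxtalk
Title: Spatially Weighted Ligand-Receptor Crosstalk Analysis for
    Imaging-Based Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying directional cell-cell communication in
    imaging-based spatial transcriptomics (CosMx-style) data. Implements
    Gaussian-kernel directional spatial proximity scores between cell
    types, spatially weighted one-to-one ligand-receptor interaction
    scores with permutation significance, nearest-landmark distance and
    radius-neighbor analyses, k-nearest-neighbor niche (neighborhood)
    composition clustering with per-niche summaries, gene-set signature
    scoring, and a seeded synthetic-data generator with planted spatial
    interactions for end-to-end validation. All results are tidy tibbles
    designed for piped workflows, with ggplot2 autoplot() methods.
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
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
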