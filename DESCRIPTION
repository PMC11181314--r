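Package: cellpaintr
Title: Morphological Profiling of Cell Painting Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for Cell Painting morphological profiling of
    compound screens. Aggregates site-level image-feature tables to well and
    replicate level, computes robust (MAD-based) Z-score profiles against
    plate-matched DMSO controls, derives induction values and activity calls,
    measures profile biosimilarity via correlation distance, selects
    reproducible features from reference-plate repeats, builds bioactivity
    cluster subprofiles by feature sign consistency and assigns compounds to
    clusters, and reproduces a compound-library curation funnel (largest
    fragment standardization, InChIKey overlap removal, availability and size
    filters, fingerprint-based MaxMin diversity selection, PAINS and
    lysosomotropism flags). Includes a synthetic-data generator with known
    ground truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    yaml,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr,
    arrow
Config/testthat/edition: 3
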