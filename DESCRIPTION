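Package: phylotrends
Title: Phylostratigraphy of Protein Domain Properties on Time-Calibrated Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for pfam-based phylostratigraphy:
    per-sequence property metrics (a normalized hydrophobic-clustering index,
    amino-acid composition, mean intrinsic disorder with optional cysteine
    excision), transmembrane classification from helix predictions, domain
    dating on time-calibrated ultrametric species trees with ancient-strata
    rules, contamination and quality filtering including a Dollo-parsimony
    Monte-Carlo test, domain co-occurrence homology grouping, and age-trend
    statistics (phylostratigraphy slopes, per-amino-acid slope profiles,
    recruitment-order correlations, minimum-age sweeps). Ships a synthetic-data
    generator that plants lineage-specific composition, disorder, and
    clustering trends so the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    broom,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
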