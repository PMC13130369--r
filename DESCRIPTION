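Package: ampliconbench
Title: Benchmarking and Optimization of 16S Metabarcoding Taxonomic Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores 16S rRNA amplicon taxonomic-classifier output against
    ground-truth mock communities. Implements taxa- and read-level
    sensitivity/selectivity, a composite surveillance score, the
    read-normalized and false-negative-weighted sum-of-absolute-errors and
    root-mean-square mapping-error families with false-positive/false-negative
    decomposition, alpha and beta diversity scoring (richness, Chao1, Shannon,
    Pielou, Bray-Curtis) with a composite diversity score and
    replicate-to-site precision ratios, and two low-read-taxon selectivity
    filters (z-score and fraction-of-total-reads). Ships a tiered
    mock-community designer, a stochastic classifier-output simulator, and
    readers/writers for Kraken 2 reports, Bracken species tables, tabular
    BLAST hits and generic taxon-count tables, so the whole evaluation
    framework runs without external pipelines.
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
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    utils,
    stats,
    vegan,
    withr
Suggests:
    Biostrings,
    S4Vectors,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
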