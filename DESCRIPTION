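Package: barcleanr
Title: Removal of Spurious Sequences from Cellular Barcoding Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and removes spurious DNA barcodes from multiplexed
    deep-sequencing read-count tables. A given PCR/sequencing error recurs at a
    near-constant rate relative to its mother barcode across all samples of a
    sequencing lane; barcleanr exploits this by scoring candidate mother-daughter
    pairs with a fixed-shape beta-binomial model of overdispersed daughter counts,
    combined with Levenshtein-distance and relative-frequency criteria, inside a
    greedy prevalence-ordered clean-up loop. Also provides FASTQ demultiplexing by
    exact primer/index matching, an in silico multi-lane reference library with a
    rescue step, performance metrics against a gold standard, randomization and
    sample-subsampling controls, and a synthetic-data generator with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    optparse,
    yaml,
    jsonlite,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
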