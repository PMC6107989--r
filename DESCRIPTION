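Package: protsketch
Title: To-Scale Protein Feature Schematics from UniProt Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fetches protein feature annotations (chains, domains, regions,
    motifs, repeats, phosphorylation sites) from the UniProt Proteins API or
    loads them offline, normalises them into a validated nine-column feature
    table, lays them out as renderer-independent to-scale geometry, and
    renders publication-style schematics of one or many proteins as
    deterministic SVG or PNG. Includes packaged fixtures, a seeded synthetic
    feature-table generator, and a command-line interface for scripted,
    reproducible figure generation.
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
    grDevices,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    GenomicRanges,
    httr,
    IRanges,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
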