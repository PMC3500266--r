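Package: adjacentome
Title: Adjacent Gene-Pair Enrichment, Co-Expression and Synteny Conservation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects immediately adjacent gene pairs within co-regulated gene
    sets (regulons), classifies their divergent/tandem/convergent orientation,
    and scores the enrichment of adjacency with a binomial tail test. Implements
    an offset-normalized Pearson correlation for expression time-courses, the
    unpaired / adjacent / paired-but-not-adjacent comparison classes, and
    bootstrap null distributions for group-average correlations. Scores the
    conservation of gene pairings across a species panel via ortholog maps,
    assigns minimal/intermediate/wide conservation classes, and estimates
    background synteny maintenance by resampling adjacent pairs. Ships a seeded
    synthetic-data generator (genomes, planted regulons, expression matrices,
    ortholog panels) so the full pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
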