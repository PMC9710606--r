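Package: swplace
Title: Alignment-Free Phylogenetic Placement with Filtered Spaced-Word Matches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Places short nucleotide reads onto a fixed, edge-weighted
    reference phylogeny without aligning them. Query-reference distances
    are estimated from spaced-word matches filtered with the HOXD70
    substitution matrix and converted to Jukes-Cantor distances; an
    attachment edge is then chosen by one of five heuristics (best-leaf by
    distance or match count, lowest-common-ancestor variants, and a
    count-ratio hybrid). Results are written in the jplace exchange
    format. Includes a seeded synthetic-data generator (Jukes-Cantor
    evolution along a tree, read fragmentation, coverage-controlled read
    bags) and a pruning-based accuracy harness using the topological node
    distance.
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
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
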