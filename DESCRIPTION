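Package: pcgkit
Title: Phylogenetic Core Group Detection and Phylogenetically
    Constrained Community Assembly Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects phylogenetic core groups (PCGs) in 16S-style
    microbial community tables: the minimal clades of a rooted phylogeny
    whose pooled abundance is present in all (or a chosen fraction of)
    samples of an ecosystem. Includes a dynamic similarity-threshold
    ladder mode built from aligned sequences or a distance matrix, a
    simulator of phylogenetically constrained community assembly
    (phylo-niches bound to clades, non-phylo-niches bound to scattered
    taxon sets, neutral within-niche lotteries, patch pooling,
    multinomial sequencing depth, alternative microbial regimes),
    community statistics (SES-MPD phylogenetic clustering signal,
    intra-group occupant turnover), and a recovery evaluator that scores
    detected groups against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    Biostrings,
    biomformat,
    optparse,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
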