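Package: ribotraffic
Title: Codon-Level Translation Bottleneck Analysis for Synonymous Expression Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes tRNA-adaptation-index (tAI) based per-codon translation
    speeds from tRNA gene copy numbers and wobble pairing constraints, locates
    and scores the slowest-translated window (the "bottleneck") of a coding
    sequence, evaluates the analytic ribosome traffic-jam condition, relates
    bottleneck geometry and per-codon usage to protein abundance and host
    fitness in synonymous-codon expression libraries (with partial-correlation
    control for mRNA folding energy), and surveys bottleneck placement across
    genomes with hypergeometric quadrant enrichment tests. Includes a seeded
    synthetic-library generator so the whole pipeline can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
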