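Package: hlenrich
Title: Drug Half-Life Analysis via Gene-Set Enrichment Profiles and
    Mutual-Information Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes drugs as vectors of hypergeometric enrichment scores
    against GO term and KEGG pathway protein-annotation sets, using
    drug-protein interaction networks in the STITCH links dialect; bins
    drugs into five biological half-life categories; ranks terms by the
    mutual information between their discretized enrichment scores and the
    category labels (the Max-Relevance criterion); and summarises selected
    terms as per-category mean-score ("level value") profiles. Ships a
    planted-signal synthetic-data generator so the full pipeline is
    testable without external downloads, plus tidy accessors, ggplot2
    autoplot() methods and a small command-line wrapper.
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
    fgsea,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
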