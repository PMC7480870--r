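Package: duplofate
Title: Evolutionary Fate Classification of Duplicated Homomeric Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for determining the interaction status and evolutionary
    fate of duplicated homomeric proteins from protein-protein interaction
    (PPI) networks and curated complex annotations. Paralogous pairs are
    detected from all-vs-all homology hit tables at three inclusive
    confidence tiers, multi-database PPI records are aggregated into
    evidence edges and passed through successive quality filters
    (mobile-element removal, bait/prey and multi-database evidence,
    sub-cellular co-localization), and each pair is assigned one of four
    divergence fates (obligatory homomer, obligatory heteromer, mixed
    homo/heteromer, hetero-others) under a stringent or flexible criterion.
    Cross-species reciprocal-homology mapping identifies heteromeric
    paralogous pairs descended from prokaryotic homomers and compares
    oligomeric orders. A seeded two-species scenario generator with known
    ground truth supports end-to-end validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
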