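Package: fpseg
Title: Forest-Prairie Chromatin Domain Segregation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistics for sequence-based chromatin domain segregation from
    Hi-C, DNA methylation, and expression data. The genome is partitioned into
    CpG-island-rich (forest) and CpG-island-poor (prairie) megabase domains;
    the package computes overall and per-domain segregation ratios,
    distance-resolved segregation, top-decile contact composition and the
    critical genomic distance, A/B compartment calls with a compartment index,
    open-sea methylation difference indices, replicate-calibrated calls of
    significantly more segregated or mixed domains, entropy-based
    lineage-specific gene selection, and a fully parameterized synthetic-data
    generator that provides ground truth for every statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
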