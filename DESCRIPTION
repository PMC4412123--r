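Package: rloopcoloc
Title: Co-Localization of R-Loops, ORC1 Binding and Replication Origins at CpG Island Promoters
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for testing whether R-loop forming regions (DRIP peaks)
    co-localize with ORC1 binding sites and short-nascent-strand (SNS)
    replication origins at CpG island promoters. Provides strand-aware
    genomic interval algebra over BED-style half-open coordinates,
    Quadparser-style G-quadruplex motif scanning, windowed GC-skew
    profiling, promoter/CpG-island association, permutation and
    interval-shuffling null models for overlap enrichment with empirical
    p-values, TSS-centered composite density profiles normalized by
    genome-wide hit density, and a seeded synthetic-genome generator with
    recorded ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
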