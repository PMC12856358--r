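Package: loopbench
Title: Comparative Benchmarking of Chromatin Loop Caller Results
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for comparative analysis of chromatin loop calls from
    Hi-C loop callers. Reads BEDPE loop calls and BED reference feature
    tracks (e.g. CTCF, H3K27ac, RNAPII peaks), computes windowed
    anchor-to-peak recovery rates and per-1000-loop recovery curves, the
    Recovery Efficiency Metric (REM), resolution-consistency scores,
    tolerance-based three-way loop overlap (Venn) counts, loop-size
    regression against matrix resolution, and a weighted aggregate score
    for ranking tools. Includes a deterministic synthetic-fixture
    generator with planted recovery fractions and designed overlap
    structure, and a job runner that writes machine-readable JSON/TSV
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
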