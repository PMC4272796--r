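Package: panelcov
Title: Coverage Audit of Clinical Gene Panels on Exome Capture Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Audits how well a clinically relevant gene panel is served by
    exome capture sequencing. Compares gene representation between a broad
    ("Known Gene"-like) and a conservative ("CCDS"-like) annotation
    database, computes per-base read-depth statistics over target regions
    (cumulative coverage curves, capture fractions at depth thresholds,
    per-gene median and interquartile summaries, inter-sample confidence
    intervals), and quantifies GC-content and gene-size drivers of coverage
    heterogeneity by linear regression. Ships a self-contained simulator of
    nested annotations, capture-kit footprints, and GC-biased multi-sample
    depth tracks so that every analysis can be exercised end to end against
    a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
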