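Package: linkcut
Title: Misassembly Correction for Draft Assemblies Using Linked-Read
    Molecule Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers the extents of large DNA molecules from barcoded
    linked-read alignments (e.g. 10x Genomics Chromium), scans every
    draft-assembly contig with a 1 bp-step sliding window for regions
    spanned by too few molecules, and cuts the draft sequences at the
    boundaries of unsupported runs, producing a corrected FASTA and a
    breakpoints BED. Ships a synthetic misassembly/linked-read scenario
    generator and a precision/recall evaluator so the whole pipeline can
    be exercised at desk scale without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    S4Vectors,
    data.table,
    stats,
    utils
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
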