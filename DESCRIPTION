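Package: cistrotype
Title: Nuclear-Receptor Cistrome-Transcriptome Integration with a
    Mappability-Aware Hotspot Peak Caller
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for nuclear-receptor ChIP-seq and
    factorial expression data. Implements a windowed binomial z-score
    ("hotspot") peak caller with input normalization, a mappability-corrected
    success probability and knockout-null peak subtraction; an eight-way
    response-type classifier for 2x2 genotype-by-ligand expression designs;
    nearest-TSS peak-to-gene assignment and direct-target set construction
    under a +/- 10 kb rule; genomic-feature and chromosome enrichment against
    genome baseline fractions; and DR1/PPRE motif construction, scanning,
    null-corrected co-occurrence and motif-similarity trees. A synthetic-data
    generator with a ground-truth manifest makes every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    data.table,
    jsonlite,
    yaml,
    ape,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
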