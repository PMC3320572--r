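Package: sasrfuse
Title: Splice Junction and Gene Fusion Discovery from RNA-Seq by
    Suffix-Array Spliced-Read Alignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects splice junctions and gene fusions from paired-end
    RNA-Seq reads using a suffix-array spliced-read (SASR) aligner over
    annotated exon boundaries.  Reads are mapped against genome, exon-exon
    junction, exon, and filter references; read pairs are scored with a
    phred-scaled pairing quality value (PQV); spanning (SPAN) and
    mate-bridging (BRIDGE) evidence is accumulated in a sparse directed
    exon graph; candidate junctions receive a Poisson-null junction
    confidence value (JCV) and are called at configurable unique-evidence
    thresholds.  Includes a parametric-bootstrap test for 5-prime bias of
    fusion breakpoints within the 5-prime partner gene and a synthetic
    genome/transcriptome/read simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
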