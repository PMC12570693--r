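Package: amplistr
Title: Amplicon Deep-Sequencing Analysis of Short Tandem Repeat and SNV
    Variation Between DNA and cDNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for targeted amplicon deep-sequencing
    studies that compare variant frequencies between two libraries amplified
    from the same locus, typically genomic DNA and cDNA derived from its
    transcript. Implements read quality control (adapter removal, 3'
    quality trimming, length filtering), a banded semi-global affine-gap
    aligner with deterministic traceback and indel left-normalisation,
    CIGAR-based extraction of repeat regions with flanking sequence,
    greedy and exact sequence clustering, (CCCT)n repeat-number calling
    with reference/deletion/insertion/complex classification and modal
    re-referencing, flanking-sequence profiling, targeted SNV allele
    frequencies, and two-sample proportion tests. Includes a synthetic
    read generator with per-molecule repeat-number variation, PCR stutter,
    sequencing error and a two-state quality model, so the whole pipeline
    is exercisable and testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    S4Vectors,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
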