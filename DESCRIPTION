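Package: polysomeAS
Title: Comparing Alternative Splicing Between Total and Polyribosomal Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare a total-RNA transcriptome against a
    polyribosome-associated (translatome) transcriptome from assembled
    transcript models and abundance estimates. Implements the two-part
    low-abundance isoform filter (FPKM and fraction-of-locus thresholds),
    classification of pairwise alternative-splicing events into the nine
    PASA-style classes merged to six categories, premature-termination-codon
    detection under the 55-nt nonsense-mediated-decay rule, retained-intron
    size and stop-codon analyses, chromosome/metagene/per-cDNA coverage
    profiles, and the comparative statistics (G-test of category proportions,
    Mann-Whitney-Wilcoxon on intron sizes, annotation matching). Includes a
    synthetic transcriptome generator that plants ground-truth splice events,
    low-abundance isoforms, PTC-bearing isoforms and uniform fragment
    coverage so the full pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
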