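Package: termread
Title: Transcription Termination Readthrough and Cleavage Kinetics Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Strand-specific analysis of transcription termination failure
    (readthrough past the poly(A) site) and its consequences for neighboring
    genes, built around an auxin-degron nascent RNA-seq design in budding
    yeast. Provides a synthetic-data generator with known ground truth
    (gene annotations with orientation relations, stranded binned coverage,
    negative-binomial count tables with S. pombe-style spike-ins, qPCR Ct
    tables, cleavage time courses), spike-in median-of-ratios normalization
    with an optional RUV-style factor-removal stage, a negative-binomial
    Wald test for strand-specific differential expression, opposite-strand
    anticorrelation and gene-orientation chi-squared statistics for
    transcription interference, metagene profiles and k-means clustering of
    convergent gene pairs at poly(A) sites, spike-in normalized delta-delta-Ct
    qPCR fold changes, and global exponential-plateau fitting of in vitro
    cleavage kinetics with analytic half-time (t50) and bootstrap confidence
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    BiocGenerics,
    rtracklayer,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
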