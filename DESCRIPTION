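Package: tbamkit
Title: Targeted Multiplexed Bacterial RNA-Seq Panel Design, Quantification
    and Depth Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational toolkit for multiplexed and targeted bacterial
    RNA-seq workflows built on in vitro polyadenylation and barcoded
    oligo(dT) reverse transcription. Designs pools of second-strand
    target-enrichment primers under length, melting-temperature, rRNA
    k-mer homology and inter-primer spacing constraints; trims poly(A)
    tails with adapter-trimming semantics; maps reads with a small
    exhaustive best-stratum aligner (or ingests external SAM/bowtie
    alignments) and applies the reverse-strand 5' position adjustment;
    quantifies expression at gene and primer level with median-primer
    summarisation; classifies chimeric mispriming events by split-read
    remapping; estimates barcode-switching (index hopping) rates from
    knockout and mixed-species designs; plans sequencing-depth
    redistribution across abundance-tiered primer pools; and simulates
    truth-tracked reads so every pipeline stage can be tested without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    rtracklayer,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
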