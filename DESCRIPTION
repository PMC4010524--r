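Package: metadraft
Title: Composition-Based Binning and Comparative Genomics of Enrichment
    Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs and compares draft genomes from enrichment
    metagenomes. Provides composition-based contig binning (GC content and
    oligonucleotide-frequency principal components with taxonomic
    uniformity filters), fragment-based average nucleotide identity (ANI)
    with a species-boundary call, fragment-recruitment profiling with
    genomic-island detection, codon-usage deviation scoring, GC-skew
    tracks, and threshold-based 16S rRNA read classification. A seeded
    synthetic-community generator with known ground truth (taxon-specific
    Markov composition models, strain pairs at planted divergence, and
    planted genomic islands excluded from a water-column read pool) makes
    every stage testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    methods,
    Rcpp,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    cluster,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
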