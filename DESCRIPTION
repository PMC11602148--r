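Package: eboxGrammar
Title: E-Box Motif Grammar Analysis for Proneural Transcription Factor Binding
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the sequence grammar of E-box motifs
    (CANNTG hexanucleotides) bound by proneural basic helix-loop-helix
    transcription factors during cortical neurogenesis. Implements
    strand-symmetric E-box classification into ten half-site classes,
    genome scanning, ChIP-seq summit centrality and spacing statistics,
    half-site flanking dinucleotide bias, single-cell ATAC pseudobulk
    trajectory classification, CpG methylation deltas around motifs,
    HT-SELEX round-wise class enrichment, and polymorphism/divergence
    selection analysis in a McDonald-Kreitman-style framework, together
    with seeded synthetic-data generators that emulate every input with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3),
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: MotifAnnotation, Epigenetics, ChIPSeq, ATACSeq, Sequencing
RoxygenNote: 7.3.3
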