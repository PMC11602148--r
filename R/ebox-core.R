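#' eboxGrammar: grammar of E-box motifs bound by proneural bHLH factors
#'
#' The package analyses CANNTG E-box hexanucleotides as they are read by
#' dimeric basic helix-loop-helix (bHLH) transcription factors: each monomer
#' contacts one CAN half-site on opposing strands, so a hexamer and its
#' reverse complement describe the same protein-facing motif.  Collapsing the
#' 16 CANNTG hexamers under this strand symmetry yields ten E-box classes,
#' named by their two 5'-3' half-sites (e.g. CAT-CAG for CAGATG/CATCTG).
#' On top of this alphabet the package provides summit-centrality, spacing
#' and flanking statistics for ChIP-seq peaks, pseudobulk accessibility
#' trajectory classification, CpG methylation deltas, HT-SELEX round-wise
#' enrichment, and polymorphism/divergence selection analysis, plus seeded
#' generators of synthetic inputs with known ground truth.
#'
#' @import methods
#' @import GenomicRanges
#' @import IRanges
#' @import S4Vectors
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement matchPattern
#'   vcountPattern readDNAStringSet writeXStringSet subseq width
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
#' @importFrom GenomeInfoDb seqlevels "seqlevels<-" seqlengths "seqlengths<-"
#' @importFrom stats oneway.test lm coef rnorm rpois rbinom runif setNames
#' @importFrom utils read.table write.table
#' @name eboxGrammar-package
#' @aliases eboxGrammar
#' @keywords internal
"_PACKAGE"

HALF_SITES <- c("CAA", "CAC", "CAG", "CAT")

## Fixed label order: the heterotypic half-site order within a label is not
## derivable from one rule, so the ten labels are pinned by a lookup table.
EBOX_LABELS <- c("CAT-CAT", "CAT-CAG", "CAT-CAC", "CAG-CAG", "CAG-CAC",
                 "CAC-CAC", "CAA-CAT", "CAA-CAG", "CAA-CAC", "CAA-CAA")

revcompChar <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

#' Enumerate the ten strand-symmetric E-box classes
#'
#' The 16 CANNTG hexamers collapse into 10 classes when a hexamer and its
#' reverse complement are identified (each bHLH monomer binds one CAN
#' half-site on opposing strands).  Classes are named by their two 5'-3'
#' half-sites.  Homotypic classes (equal half-sites) are their own reverse
#' complement and have a single representative hexamer; heterotypic classes
#' have two.
#'
#' @return A `data.frame` with one row per class in a fixed canonical order:
#'   `label`, `half_a`, `half_b`, `representatives` (comma-separated
#'   forward-strand hexamers), `n_representatives`.
#' @examples
#' eboxClasses()
#' @export
eboxClasses <- function() {
  hex <- eboxHexamers()
  half_a <- substr(hex, 1, 3)
  half_b <- revcompChar(substr(hex, 4, 6))
  key <- mapply(function(a, b) paste(sort(c(a, b)), collapse = ":"),
                half_a, half_b)
  lab_half <- strsplit(EBOX_LABELS, "-", fixed = TRUE)
  lab_key <- vapply(lab_half, function(h) paste(sort(h), collapse = ":"), "")
  reps <- vapply(lab_key, function(k)
    paste(sort(unique(hex[key == k])), collapse = ","), "")
  data.frame(
    label = EBOX_LABELS,
    half_a = vapply(lab_half, `[`, "", 1L),
    half_b = vapply(lab_half, `[`, "", 2L),
    representatives = unname(reps),
    n_representatives = lengths(strsplit(unname(reps), ",", fixed = TRUE)),
    stringsAsFactors = FALSE
  )
}

#' All 16 forward-strand CANNTG hexamers
#' @return Character vector of the 16 hexamers of form CANNTG.
#' @export
eboxHexamers <- function() {
  nn <- expand.grid(n1 = c("A", "C", "G", "T"), n2 = c("A", "C", "G", "T"),
                    stringsAsFactors = FALSE)
  paste0("CA", nn$n1, nn$n2, "TG")
}

.classLookup <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      cls <- eboxClasses()
      reps <- strsplit(cls$representatives, ",", fixed = TRUE)
      tab <<- setNames(rep(cls$label, lengths(reps)), unlist(reps))
    }
    tab
  }
})

#' Canonical E-box class of a hexamer
#'
#' Maps a hexanucleotide to its strand-symmetric E-box class label, i.e.
#' `canonicalClass(x) == canonicalClass(reverseComplement(x))`.  Hexamers not
#' of the form CANNTG (including any with N at the four fixed positions)
#' return `NA`.
#'
#' @param hexamer Character vector of length-6 strings over A,C,G,T,N.
#' @return Character vector of class labels (or `NA`), same length as input.
#' @examples
#' canonicalClass("CAGATG")  # "CAT-CAG"
#' canonicalClass(c("CATATG", "AAAAAA"))
#' @export
canonicalClass <- function(hexamer) {
  hexamer <- toupper(hexamer)
  if (any(nchar(hexamer) != 6L))
    stop("all hexamers must have length 6")
  lookup <- .classLookup()
  out <- unname(lookup[hexamer])
  miss <- is.na(out) & grepl("^CA[ACGT][ACGT]TG$", hexamer)
  if (any(miss))  # reverse-strand spelling of a representative
    out[miss] <- unname(lookup[revcompChar(hexamer[miss])])
  out
}

#' Scan a sequence for E-box occurrences
#'
#' Exact pattern matching of CANNTG on the forward strand.  Forward-only
#' scanning is complete: a reverse-strand E-box is also a forward-strand
#' E-box, and canonicalization absorbs the strand.  Overlapping occurrences
#' are all reported.  N at any of the six core positions blocks a match.
#'
#' @param sequence A character string or [Biostrings::DNAString] to scan.
#' @param contig Sequence name for the returned ranges.
#' @param offset 0-based offset of the first base of `sequence` on `contig`
#'   (so a site at string position i, 1-based, gets start `offset + i`).
#' @return A [GenomicRanges::GRanges] of width-6 sites with metadata columns
#'   `hexamer`, `ebox_class`, `flank_a`, `flank_b` (upstream dinucleotides of
#'   the forward and reverse-strand half-sites; "NN"-padded at sequence ends).
#' @examples
#' scanEBoxes("GCCAGATGCT")
#' @export
scanEBoxes <- function(sequence, contig = "seq1", offset = 0L) {
  seq <- if (is(sequence, "DNAString")) sequence else DNAString(as.character(sequence))
  if (length(seq) < 6L) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(hexamer = character(0), ebox_class = character(0),
                           flank_a = character(0), flank_b = character(0))
    return(gr)
  }
  m <- matchPattern("CANNTG", seq, fixed = FALSE)
  # fixed=FALSE lets N in the subject match the pattern's wildcards; drop
  # any hit whose realised hexamer is not a clean CANNTG over A/C/G/T
  hex <- as.character(m)
  keep <- grepl("^CA[ACGT][ACGT]TG$", hex)
  st <- start(m)[keep]
  hex <- hex[keep]
  if (length(st) == 0L) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(hexamer = character(0), ebox_class = character(0),
                           flank_a = character(0), flank_b = character(0))
    return(gr)
  }
  fl <- .flanksAt(as.character(seq), st)
  gr <- GRanges(contig, IRanges(start = st + offset, width = 6L))
  mcols(gr) <- DataFrame(hexamer = hex,
                         ebox_class = canonicalClass(hex),
                         flank_a = fl$flank_a, flank_b = fl$flank_b)
  gr
}

## upstream dinucleotides of both half-sites for hexamer starts `st`
## (1-based within `seqchar`); out-of-bounds positions padded with N
.flanksAt <- function(seqchar, st) {
  n <- nchar(seqchar)
  padded <- paste0("NN", seqchar, "NN")
  flank_a <- substr(rep(padded, length.out = length(st)), st, st + 1L)
  right <- substr(rep(padded, length.out = length(st)), st + 8L, st + 9L)
  flank_b <- if (length(st)) revcompChar(right) else character(0)
  list(flank_a = flank_a, flank_b = flank_b)
}

#' Upstream dinucleotide flanks of both half-sites
#'
#' For a site at `start` (1-based) the forward half-site flank is the
#' dinucleotide immediately 5' of the hexamer; the reverse half-site flank is
#' the reverse complement of the two bases immediately 3' (i.e. the upstream
#' dinucleotide read 5'-3' on the reverse strand).  Positions outside the
#' sequence yield "N".
#'
#' @param sequence Character string containing the site.
#' @param start 1-based start position(s) of the hexamer(s).
#' @return A `data.frame` with columns `flank_a` and `flank_b`.
#' @examples
#' halfSiteFlanks("GCCAGATGCT", 3)  # flank_a "GC", flank_b "AG"
#' @export
halfSiteFlanks <- function(sequence, start) {
  fl <- .flanksAt(as.character(sequence), as.integer(start))
  data.frame(flank_a = fl$flank_a, flank_b = fl$flank_b,
             stringsAsFactors = FALSE)
}

#' Scan a set of sequences for E-boxes
#'
#' @param seqs A named [Biostrings::DNAStringSet] (names become contigs).
#' @return Concatenated [GenomicRanges::GRanges] of sites from [scanEBoxes].
#' @export
scanEBoxSet <- function(seqs) {
  stopifnot(is(seqs, "DNAStringSet"))
  nm <- names(seqs)
  if (is.null(nm)) nm <- paste0("seq", seq_along(seqs))
  grl <- lapply(seq_along(seqs), function(i) {
    gr <- scanEBoxes(seqs[[i]], contig = nm[i])
    seqlevels(gr) <- nm
    gr
  })
  out <- do.call(c, grl)
  seqlengths(out) <- width(seqs)
  out
}

#' Signed summit distances for E-box sites
#'
#' Associates each site with the peak containing it and records the signed
#' distance from the hexamer midpoint to the peak summit (midpoint - summit).
#' Sites in no peak get `NA`.  The midpoint of a width-6 site is
#' `floor((start + end)/2)`.
#'
#' @param sites `GRanges` of E-box sites (from [scanEBoxes]).
#' @param peaks `GRanges` of peaks with an integer `summit` metadata column
#'   (absolute 1-based position).
#' @return `sites` with added metadata columns `peak_id` (index into `peaks`)
#'   and `summit_distance`.
#' @export
annotateSummitDistance <- function(sites, peaks) {
  stopifnot(!is.null(peaks$summit))
  # sites on contigs absent from the peak set simply get NA distances
  hits <- suppressWarnings(
    findOverlaps(sites, peaks, type = "within", select = "first"))
  mid <- floor((start(sites) + end(sites)) / 2)
  sites$peak_id <- hits
  sites$summit_distance <- ifelse(is.na(hits), NA_integer_,
                                  mid - peaks$summit[hits])
  sites
}
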