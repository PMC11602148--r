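## HT-SELEX round-wise E-box class enrichment: the fraction of reads in
## each selection round carrying at least one representative hexamer of
## each class, and its trend across rounds.

#' SelexRounds: ordered HT-SELEX selection rounds
#'
#' Holds the fixed-length reads of each successive selection round as a list
#' of [Biostrings::DNAStringSet]s, ordered round 1..R.
#'
#' @slot reads List of `DNAStringSet`, one per round.
#' @slot round Integer round indices.
#' @export
setClass("SelexRounds",
         representation(reads = "list", round = "integer"))

setValidity("SelexRounds", function(object) {
  if (length(object@reads) != length(object@round))
    return("one read set per round required")
  if (length(object@round) && any(diff(object@round) <= 0))
    return("rounds must be strictly increasing")
  if (!all(vapply(object@reads, function(x) is(x, "DNAStringSet"), TRUE)))
    return("reads must be DNAStringSet objects")
  if (any(vapply(object@reads, length, 0L) == 0L))
    return("every round must contain reads")
  TRUE
})

#' Construct a SelexRounds object
#' @param reads List of `DNAStringSet` (or character vectors), round order.
#' @param round Round indices (default `seq_along(reads)`).
#' @return A [SelexRounds-class] object.
#' @export
SelexRounds <- function(reads, round = seq_along(reads)) {
  reads <- lapply(reads, function(x)
    if (is(x, "DNAStringSet")) x else DNAStringSet(x))
  new("SelexRounds", reads = reads, round = as.integer(round))
}

setMethod("show", "SelexRounds", function(object) {
  cat("SelexRounds:", length(object@round), "rounds;",
      paste0("round ", object@round, ": ",
             vapply(object@reads, length, 0L), " reads",
             collapse = "; "), "\n")
})

#' Number of rounds
#' @param x A `SelexRounds`.
#' @return Integer.
#' @export
nRounds <- function(x) length(x@round)

#' Reads of one round
#' @param x A `SelexRounds`.
#' @param i Round position.
#' @return `DNAStringSet`.
#' @export
roundReads <- function(x, i) x@reads[[i]]

#' Read SELEX rounds from a manifest of FASTA/FASTQ files
#'
#' @param manifest `data.frame` with columns `round` and `path` (FASTA
#'   files, gzip-transparent).
#' @return A [SelexRounds-class] object.
#' @export
readSelexRounds <- function(manifest) {
  ord <- order(manifest$round)
  reads <- lapply(manifest$path[ord], readDNAStringSet)
  SelexRounds(reads, round = manifest$round[ord])
}

#' Fraction of reads carrying each E-box class, per round
#'
#' For each round and class, the fraction of reads containing at least one
#' occurrence of any representative hexamer of the class, matched on the
#' forward strand (matching both representatives makes the detection
#' strand-insensitive).  A read can count toward several classes.  Reads
#' shorter than 6 bases are skipped with a warning; N never matches.
#'
#' @param rounds A [SelexRounds-class] object.
#' @return Numeric matrix, classes x rounds, values in [0, 1].
#' @export
roundClassFractions <- function(rounds) {
  stopifnot(is(rounds, "SelexRounds"))
  cls <- eboxClasses()
  reps <- strsplit(cls$representatives, ",", fixed = TRUE)
  out <- matrix(NA_real_, nrow = nrow(cls), ncol = nRounds(rounds),
                dimnames = list(cls$label,
                                paste0("round", rounds@round)))
  for (j in seq_len(nRounds(rounds))) {
    reads <- roundReads(rounds, j)
    short <- width(reads) < 6L
    if (any(short)) {
      warning(sum(short), " read(s) shorter than 6 bases skipped in round ",
              rounds@round[j])
      reads <- reads[!short]
    }
    n <- length(reads)
    for (k in seq_len(nrow(cls))) {
      has <- rep(FALSE, n)
      for (p in reps[[k]])
        has <- has | vcountPattern(p, reads, fixed = TRUE) > 0L
      out[k, j] <- sum(has) / n
    }
  }
  out
}

#' Enrichment trend of class fractions across rounds
#'
#' Per class: the least-squares slope of the fraction against round index, a
#' strict-monotone-increase flag, the relative growth (last/first round),
#' and an `enriched` call requiring both a strictly monotone increase and a
#' relative growth above `growth_min` -- plain monotonicity alone is met by
#' neutral round-to-round drift with appreciable probability.
#'
#' @param fractions Class x round matrix from [roundClassFractions].
#' @param growth_min Minimum last/first fraction ratio for an `enriched`
#'   call (default 1.5).
#' @return `data.frame` per class: `slope`, `monotone`, `growth`,
#'   `enriched`.
#' @export
enrichmentTrend <- function(fractions, growth_min = 1.5) {
  stopifnot(ncol(fractions) >= 2L)
  idx <- seq_len(ncol(fractions))
  slope <- apply(fractions, 1, function(f) unname(coef(lm(f ~ idx))[2L]))
  monotone <- apply(fractions, 1, function(f) all(diff(f) > 0))
  growth <- apply(fractions, 1, function(f)
    if (f[1L] > 0) f[length(f)] / f[1L] else ifelse(f[length(f)] > 0, Inf, NA))
  data.frame(ebox_class = rownames(fractions), slope = slope,
             monotone = monotone, growth = growth,
             enriched = monotone & !is.na(growth) & growth > growth_min,
             row.names = NULL, stringsAsFactors = FALSE)
}
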