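## shared fixture builders; everything is generated in code

rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

randomSeq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## brute-force oracle: group all 4096 hexamers by reverse-complement
## equivalence and keep the CANNTG ones
bruteForceClasses <- function() {
  b <- c("A", "C", "G", "T")
  hex <- do.call(paste0, expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE))
  ebox <- hex[grepl("^CA..TG$", hex)]
  key <- vapply(ebox, function(h) paste(sort(c(h, rc(h))), collapse = "|"), "")
  split(ebox, key)
}

peaksGR <- function(starts, ends, summits, contig = "chr1") {
  gr <- GRanges(contig, IRanges(starts, ends))
  gr$summit <- as.integer(summits)
  gr
}

sitesGR <- function(classes, summit_distance, peak_id = 1L, contig = "chrT") {
  n <- length(classes)
  gr <- GRanges(contig, IRanges(seq(1, by = 50, length.out = n), width = 6L))
  gr$ebox_class <- classes
  gr$summit_distance <- as.integer(summit_distance)
  gr$peak_id <- rep(peak_id, length.out = n)
  gr
}
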