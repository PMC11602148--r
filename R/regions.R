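## Genomic interval and signal plumbing: peak IO, summit-centred resizing,
## the two-replicate consensus rule, and anchor-centred signal matrices.
## All in-memory coordinates are 1-based closed (GRanges); BED-family files
## are converted on read/write.

#' Read an ENCODE narrowPeak file
#'
#' 10-column BED6+4; the col-10 summit offset is converted to an absolute
#' 1-based `summit` position (`start + offset` in 0-based, i.e.
#' `start(gr) + offset` here).
#'
#' @param path Path to a narrowPeak file (plain or gzip).
#' @return `GRanges` with metadata columns `name`, `score`, `signalValue`,
#'   `pValue`, `qValue`, `summit`.
#' @export
readNarrowPeak <- function(path) {
  cols <- c(signalValue = "numeric", pValue = "numeric",
            qValue = "numeric", peak = "integer")
  gr <- rtracklayer::import(path, format = "BED", extraCols = cols)
  gr$summit <- start(gr) + gr$peak
  gr$peak <- NULL
  gr
}

#' Write peaks as narrowPeak
#'
#' @param peaks `GRanges` with a `summit` column (absolute, 1-based).
#' @param path Output path.
#' @export
writeNarrowPeak <- function(peaks, path) {
  df <- data.frame(
    chrom = as.character(seqnames(peaks)),
    start = start(peaks) - 1L,
    end = end(peaks),
    name = if (!is.null(peaks$name)) peaks$name else paste0("peak_", seq_along(peaks)),
    score = if (!is.null(peaks$score)) peaks$score else 0,
    strand = ".",
    signalValue = if (!is.null(peaks$signalValue)) peaks$signalValue else 0,
    pValue = -1, qValue = -1,
    peak = peaks$summit - start(peaks)
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' @param path Path to a bedGraph file (plain or gzip).
#' @return `GRanges` with a numeric `score` column.
#' @export
readBedGraph <- function(path) {
  rtracklayer::import(path, format = "bedGraph")
}

#' Write a signal track as bedGraph
#' @param track `GRanges` with `score`.
#' @param path Output path.
#' @export
writeBedGraph <- function(track, path) {
  rtracklayer::export(track, path, format = "bedGraph")
  invisible(path)
}

#' Consensus peaks from two replicates
#'
#' A consensus peak is kept for every intersecting pair of replicate peaks
#' whose interval intersection contains both summits.  The consensus interval
#' is the intersection and its summit is the floor of the two summits'
#' midpoint.  Overlapping consensus records (one peak intersecting several in
#' the other replicate) are merged by union, keeping the leftmost summit.
#'
#' @param rep_a,rep_b `GRanges` with `summit` metadata columns.
#' @return `GRanges` of consensus peaks with a `summit` column.
#' @export
consensusPeaks <- function(rep_a, rep_b) {
  stopifnot(!is.null(rep_a$summit), !is.null(rep_b$summit))
  hits <- findOverlaps(rep_a, rep_b)
  if (length(hits) == 0L) {
    out <- GRanges()
    out$summit <- integer(0)
    return(out)
  }
  a <- rep_a[queryHits(hits)]
  b <- rep_b[subjectHits(hits)]
  is <- pmax(start(a), start(b))
  ie <- pmin(end(a), end(b))
  sa <- a$summit
  sb <- b$summit
  keep <- sa >= is & sa <= ie & sb >= is & sb <= ie
  if (!any(keep)) {
    out <- GRanges()
    out$summit <- integer(0)
    return(out)
  }
  cons <- GRanges(seqnames(a)[keep], IRanges(is[keep], ie[keep]))
  cons$summit <- as.integer(floor((sa[keep] + sb[keep]) / 2))
  cons <- sort(cons)
  merged <- reduce(cons, with.revmap = TRUE)
  merged$summit <- vapply(merged$revmap, function(i) min(cons$summit[i]), 0L)
  merged$revmap <- NULL
  merged
}

#' Resize peaks to a fixed width around their summits
#'
#' Each peak becomes the `width`-bp window centred on its summit.  If contig
#' lengths are known (via `seqlengths` or the `contig_lengths` argument) the
#' window is clipped at contig bounds and flagged.
#'
#' @param peaks `GRanges` with `summit`.
#' @param width Target width in bp.
#' @param contig_lengths Optional named vector of contig lengths.
#' @return `GRanges` with `summit` and logical `clipped` columns.
#' @export
resizeToSummit <- function(peaks, width, contig_lengths = NULL) {
  stopifnot(width > 0, !is.null(peaks$summit))
  half <- width / 2
  ## 0-based half-open [summit - w/2, summit + w/2) => 1-based closed
  new_start <- as.integer(floor(peaks$summit - half))
  new_end <- as.integer(floor(peaks$summit + half) - 1L)
  lens <- contig_lengths
  if (is.null(lens)) lens <- seqlengths(peaks)
  clipped <- rep(FALSE, length(peaks))
  low <- new_start < 1L
  clipped <- clipped | low
  new_start[low] <- 1L
  if (!is.null(lens) && any(!is.na(lens))) {
    lim <- lens[as.character(seqnames(peaks))]
    high <- !is.na(lim) & new_end > lim
    clipped <- clipped | high
    new_end[high] <- lim[high]
  }
  out <- GRanges(seqnames(peaks), IRanges(new_start, new_end))
  out$summit <- peaks$summit
  out$clipped <- clipped
  out
}

#' Anchor-centred binned signal matrix
#'
#' Entry (i, j) is the mean track value over the base pairs of bin j within
#' the window `[anchor_i - flank, anchor_i + flank)` (0-based half-open,
#' `2*flank/bin` bins).  Only base pairs covered by the track contribute;
#' bins with no data are `NA`.
#'
#' @param track `GRanges` with `score` (non-overlapping intervals).
#' @param anchors `GRanges` of width-1 anchor positions or integer positions
#'   with `contigs` supplied.
#' @param flank Half-window in bp (multiple of `bin`).
#' @param bin Bin width in bp.
#' @param contigs Contig names if `anchors` is an integer vector.
#' @return Numeric matrix, anchors x bins; columns named by the bin-centre
#'   offset from the anchor.
#' @export
signalMatrix <- function(track, anchors, flank, bin = 1L, contigs = NULL) {
  if (!is(anchors, "GRanges")) {
    stopifnot(!is.null(contigs))
    anchors <- GRanges(contigs, IRanges(as.integer(anchors), width = 1L))
  }
  stopifnot(flank %% bin == 0)
  nbin <- as.integer(2 * flank / bin)
  offs <- seq(-flank, flank - bin, by = bin)
  n <- length(anchors)
  out <- matrix(NA_real_, nrow = n, ncol = nbin,
                dimnames = list(NULL, offs + (bin - 1) / 2))
  if (n == 0L || length(track) == 0L) return(out)
  anchor_pos <- start(anchors)
  ## expand: one range per (anchor, bin)
  bin_start <- rep(anchor_pos, each = nbin) + rep(offs, n)
  bins <- GRanges(rep(as.character(seqnames(anchors)), each = nbin),
                  IRanges(bin_start, width = bin))
  hits <- findOverlaps(bins, track)
  if (length(hits)) {
    ov <- pintersect(bins[queryHits(hits)], track[subjectHits(hits)])
    w <- width(ov)
    v <- track$score[subjectHits(hits)]
    num <- tapply(w * v, queryHits(hits), sum)
    den <- tapply(w, queryHits(hits), sum)
    idx <- as.integer(names(num))
    out[cbind((idx - 1L) %/% nbin + 1L, (idx - 1L) %% nbin + 1L)] <- num / den
  }
  out
}

#' Scaled Jaccard indices between peak sets
#'
#' Jaccard = overlapping bp / union bp for each (query, reference) pair of
#' interval sets; each query row is then divided by its row maximum so the
#' best-matching reference scores exactly 1.
#'
#' @param query_sets,reference_sets Named lists of `GRanges`.
#' @param scale Divide each row by its maximum (default TRUE).
#' @return Numeric matrix, queries x references.
#' @export
scaledJaccard <- function(query_sets, reference_sets, scale = TRUE) {
  jac <- function(a, b) {
    a <- reduce(a); b <- reduce(b)
    inter <- sum(width(GenomicRanges::intersect(a, b)))
    uni <- sum(width(GenomicRanges::union(a, b)))
    if (uni == 0) 0 else inter / uni
  }
  m <- matrix(0, length(query_sets), length(reference_sets),
              dimnames = list(names(query_sets), names(reference_sets)))
  for (i in seq_along(query_sets))
    for (j in seq_along(reference_sets))
      m[i, j] <- jac(query_sets[[i]], reference_sets[[j]])
  if (scale) {
    rm <- apply(m, 1, max)
    rm[rm == 0] <- 1
    m <- m / rm
  }
  m
}
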