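## CpG methylation profiling around peaks and E-boxes, and cell-stage
## deltas.  Tracks are %CpG methylation in [0, 100], held as GRanges with a
## `score` column; only covered base pairs (CpG positions with data) enter
## any mean.

#' Mean methylation profile around anchors
#'
#' Builds the anchor x bin matrix with [signalMatrix] and summarizes each
#' bin column as mean and standard error over the anchors with data.
#'
#' @param tracks Named list of `GRanges` methylation tracks (one per stage),
#'   or a single `GRanges`.
#' @param anchors `GRanges` of summits or E-box midpoints (width 1).
#' @param flank Half-window in bp.
#' @param bin Bin width in bp (study value 10).
#' @return `data.frame`: `stage`, `offset` (bin centre), `mean`, `sem`, `n`.
#' @export
methylationProfile <- function(tracks, anchors, flank = 1500, bin = 10) {
  if (is(tracks, "GRanges")) tracks <- list(track = tracks)
  out <- lapply(names(tracks), function(st) {
    m <- signalMatrix(tracks[[st]], anchors, flank = flank, bin = bin)
    n <- colSums(!is.na(m))
    mu <- suppressWarnings(colMeans(m, na.rm = TRUE))
    mu[n == 0] <- NA_real_
    sem <- apply(m, 2, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2L) return(NA_real_)
      sd(v) / sqrt(length(v))
    })
    data.frame(stage = st, offset = as.numeric(colnames(m)),
               mean = mu, sem = sem, n = n, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Per-class methylation delta between two stages around E-boxes
#'
#' For each E-box class, the mean %CpG methylation over covered base pairs
#' within `halfwidth` bp of the hexamer midpoint is computed per stage; the
#' delta is stage B minus stage A (percentage points).  Classes with no
#' covered CpG in either stage are `NA`.
#'
#' @param track_a,track_b Methylation `GRanges` for stages A (e.g. NSC) and
#'   B (e.g. PN).
#' @param sites E-box `GRanges` with `ebox_class`.
#' @param halfwidth Window half-width around the hexamer midpoint (study
#'   value 5 bp, an 11-bp window).
#' @return `data.frame` per class: `mean_a`, `mean_b`, `delta`, `n_bp_a`,
#'   `n_bp_b`.
#' @export
eboxMethylationDelta <- function(track_a, track_b, sites, halfwidth = 5) {
  mid <- floor((start(sites) + end(sites)) / 2)
  win <- GRanges(seqnames(sites), IRanges(mid - halfwidth, mid + halfwidth))
  cls <- .siteClasses(sites)
  stageMean <- function(track) {
    hits <- findOverlaps(win, track)
    if (length(hits) == 0L)
      return(list(mean = setNames(rep(NA_real_, length(EBOX_LABELS)),
                                  EBOX_LABELS),
                  nbp = setNames(rep(0L, length(EBOX_LABELS)), EBOX_LABELS)))
    ov <- pintersect(win[queryHits(hits)], track[subjectHits(hits)])
    w <- width(ov)
    v <- track$score[subjectHits(hits)]
    k <- cls[queryHits(hits)]
    num <- tapply(w * v, k, sum)
    den <- tapply(w, k, sum)
    list(mean = num / den,
         nbp = setNames(as.integer(ifelse(is.na(den), 0L, den)), names(den)))
  }
  a <- stageMean(track_a)
  b <- stageMean(track_b)
  data.frame(ebox_class = EBOX_LABELS,
             mean_a = as.numeric(a$mean[EBOX_LABELS]),
             mean_b = as.numeric(b$mean[EBOX_LABELS]),
             delta = as.numeric(b$mean[EBOX_LABELS]) -
               as.numeric(a$mean[EBOX_LABELS]),
             n_bp_a = as.integer(a$nbp[EBOX_LABELS]),
             n_bp_b = as.integer(b$nbp[EBOX_LABELS]),
             stringsAsFactors = FALSE)
}
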