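## Divergence/diversity selection analysis of E-boxes: polymorphism and
## substitution counting, distance-binned variation, PSS/NSS ratios,
## McDonald-Kreitman-style quadrant resampling and phylostratigraphic
## depth.  PSS = putatively selected sites (E-boxes within 50 bp of the
## summit); NSS = non-selected sites (200-400 bp away).

CLADE_LEVELS <- c("placental", "marsupial", "monotreme", "non_mammal")

#' Default clade scheme for phylostratigraphic depth
#'
#' Required conserved species per clade, over the clade's species total:
#' 20/39 placental mammals, 1/3 marsupials, 1/1 monotreme, 8/16 non-mammals.
#'
#' @return `data.frame`: `clade`, `required`, `total` (shallow to deep).
#' @export
cladeScheme <- function() {
  data.frame(clade = CLADE_LEVELS,
             required = c(20L, 1L, 1L, 8L),
             total = c(39L, 3L, 1L, 16L),
             stringsAsFactors = FALSE)
}

#' Count qualifying polymorphisms per E-box site
#'
#' SNVs with minor allele frequency >= `maf_min` (inclusive, per the rule
#' "superior or equal to 0.05") falling within the hexamer are counted.
#'
#' @param sites E-box `GRanges`.
#' @param variants `data.frame` with `contig`, `position` (1-based), `ref`,
#'   `alt`, `maf`, or a `GRanges` with `maf` (SNVs only).
#' @param maf_min Inclusive MAF threshold (study value 0.05).
#' @return Integer vector of per-site counts.
#' @export
countPolymorphisms <- function(sites, variants, maf_min = 0.05) {
  if (!is(variants, "GRanges")) {
    snv <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L
    variants <- variants[snv, , drop = FALSE]
    vgr <- GRanges(variants$contig,
                   IRanges(as.integer(variants$position), width = 1L),
                   maf = variants$maf)
  } else vgr <- variants
  vgr <- vgr[vgr$maf >= maf_min]
  countOverlaps(sites, vgr)
}

#' Count substitutions against an outgroup, excluding indel-spanning motifs
#'
#' For each site, the aligned reference and outgroup hexamers are compared
#' base by base; mismatches are counted.  Any gap within the hexamer (in
#' either sequence) excludes the motif (`NA` with `excluded = "indel"`);
#' motifs not covered by the alignment are excluded with a distinct flag.
#'
#' @param ref_seq,outgroup_seq Character vectors of aligned hexamer strings
#'   (length 6, gap symbol "-" allowed), one pair per site; `NA` in
#'   `outgroup_seq` marks an uncovered motif.
#' @return `data.frame`: `substitutions` (NA when excluded), `excluded`
#'   (`"no"`, `"indel"` or `"uncovered"`).
#' @export
countSubstitutions <- function(ref_seq, outgroup_seq) {
  stopifnot(length(ref_seq) == length(outgroup_seq))
  n <- length(ref_seq)
  subs <- rep(NA_integer_, n)
  excl <- rep("no", n)
  uncov <- is.na(outgroup_seq)
  excl[uncov] <- "uncovered"
  gap <- !uncov & (grepl("-", ref_seq, fixed = TRUE) |
                     grepl("-", outgroup_seq, fixed = TRUE))
  excl[gap] <- "indel"
  ok <- which(excl == "no")
  if (length(ok)) {
    a <- strsplit(toupper(ref_seq[ok]), "")
    b <- strsplit(toupper(outgroup_seq[ok]), "")
    subs[ok] <- mapply(function(x, y) sum(x != y), a, b)
  }
  data.frame(substitutions = subs, excluded = excl,
             stringsAsFactors = FALSE)
}

#' Variation binned by distance to the summit
#'
#' Mean and standard deviation of per-site counts (substitutions or
#' polymorphisms) in bins of |summit distance|.
#'
#' @param summit_distance Signed distances (bp) per site.
#' @param counts Per-site counts (`NA` = excluded site).
#' @param bin_width Bin width in bp.
#' @param max_distance Outer bound on |d|.
#' @return `data.frame`: `bin_mid`, `mean`, `sd`, `n` (empty bins `NA`).
#' @export
distanceBinnedVariation <- function(summit_distance, counts,
                                    bin_width = 50, max_distance = 500) {
  d <- abs(summit_distance)
  keep <- !is.na(d) & !is.na(counts) & d <= max_distance
  breaks <- seq(0, max_distance, by = bin_width)
  bin <- cut(d[keep], breaks, include.lowest = TRUE, right = TRUE)
  mu <- tapply(counts[keep], bin, mean)
  sdv <- tapply(counts[keep], bin, sd)
  n <- tapply(counts[keep], bin, length)
  data.frame(bin_mid = (head(breaks, -1) + tail(breaks, -1)) / 2,
             mean = as.numeric(mu), sd = as.numeric(sdv),
             n = as.integer(ifelse(is.na(n), 0L, n)))
}

#' PSS/NSS selection rate ratios per E-box class
#'
#' Per class, the rate (counts per motif) among putatively selected sites
#' (|d| <= `pss_halfwidth`) and among non-selected sites (|d| in
#' `nss_range`, bounds inclusive), and their ratio, for polymorphism (p) and
#' divergence (d) counts.  Excluded sites (NA counts) drop out of the rate
#' for that measure; a class with no NSS motifs gets `NA` ratios.
#'
#' @param ebox_class Per-site class labels.
#' @param summit_distance Per-site signed summit distances.
#' @param poly_counts,div_counts Per-site polymorphism and substitution
#'   counts (either may be NULL).
#' @param pss_halfwidth PSS window (study value 50).
#' @param nss_range NSS |d| bounds (study values 200-400).
#' @return `data.frame` per class: `n_pss`, `n_nss`, `pPSS`, `pNSS`,
#'   `dPSS`, `dNSS`, `p_ratio`, `d_ratio`.
#' @export
pssNssRatios <- function(ebox_class, summit_distance, poly_counts = NULL,
                         div_counts = NULL, pss_halfwidth = 50,
                         nss_range = c(200, 400)) {
  stopifnot(nss_range[1] > pss_halfwidth, nss_range[2] > nss_range[1])
  d <- abs(summit_distance)
  in_pss <- !is.na(d) & d <= pss_halfwidth
  in_nss <- !is.na(d) & d >= nss_range[1] & d <= nss_range[2]
  cls <- factor(ebox_class, levels = EBOX_LABELS)
  rate <- function(counts, sel) {
    if (is.null(counts)) return(rep(NA_real_, length(EBOX_LABELS)))
    ok <- sel & !is.na(counts)
    tot <- tapply(counts[ok], cls[ok], sum)
    n <- tapply(counts[ok], cls[ok], length)
    as.numeric(tot) / as.numeric(n)
  }
  out <- data.frame(
    ebox_class = EBOX_LABELS,
    n_pss = as.integer(table(cls[in_pss])),
    n_nss = as.integer(table(cls[in_nss])),
    pPSS = rate(poly_counts, in_pss), pNSS = rate(poly_counts, in_nss),
    dPSS = rate(div_counts, in_pss), dNSS = rate(div_counts, in_nss),
    stringsAsFactors = FALSE)
  out$p_ratio <- ifelse(!is.na(out$pNSS) & out$pNSS > 0,
                        out$pPSS / out$pNSS, NA_real_)
  out$d_ratio <- ifelse(!is.na(out$dNSS) & out$dNSS > 0,
                        out$dPSS / out$dNSS, NA_real_)
  out
}

#' McDonald-Kreitman-style ratio resampling per class
#'
#' For each of `n_subsets` seeded random subsets of a class's sites (sampled
#' without replacement), both the polymorphism and divergence PSS/NSS ratios
#' are recomputed; a subset lands in the "purifying" quadrant iff both
#' ratios are < 1.
#'
#' @param ebox_class,summit_distance,poly_counts,div_counts Per-site inputs
#'   as in [pssNssRatios].
#' @param classes Classes to resample (default: all with sites).
#' @param n_subsets Number of subsets per class.
#' @param subset_size Sites per subset (default: half the class's sites).
#' @param seed Seed for reproducible sampling.
#' @param ... Window bounds passed to [pssNssRatios].
#' @return `data.frame`: `ebox_class`, `subset`, `p_ratio`, `d_ratio`,
#'   `quadrant`.
#' @export
mkResample <- function(ebox_class, summit_distance, poly_counts, div_counts,
                       classes = NULL, n_subsets = 100L, subset_size = NULL,
                       seed = 1L, ...) {
  set.seed(seed)
  if (is.null(classes))
    classes <- intersect(EBOX_LABELS, unique(ebox_class))
  res <- list()
  for (cl in classes) {
    idx <- which(ebox_class == cl)
    sz <- if (is.null(subset_size)) max(2L, length(idx) %/% 2L) else subset_size
    stopifnot(sz <= length(idx))
    for (s in seq_len(n_subsets)) {
      i <- sample(idx, sz)
      r <- pssNssRatios(ebox_class[i], summit_distance[i],
                        poly_counts[i], div_counts[i], ...)
      r <- r[r$ebox_class == cl, ]
      res[[length(res) + 1L]] <- data.frame(
        ebox_class = cl, subset = s,
        p_ratio = r$p_ratio, d_ratio = r$d_ratio,
        quadrant = ifelse(!is.na(r$p_ratio) & !is.na(r$d_ratio) &
                            r$p_ratio < 1 & r$d_ratio < 1,
                          "purifying", "other"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

#' Per-species conservation status of a motif
#'
#' A motif is conserved in a species iff its aligned string equals the
#' reference at all six core positions; any gap (in the species string)
#' excludes it; otherwise it is diverged.  Species absent from the block are
#' excluded.
#'
#' @param ref Reference hexamer (gap-free CANNTG).
#' @param aligned Named character vector: species -> aligned length-6 string
#'   (`NA` = missing).
#' @return Named character vector: species -> "conserved" / "diverged" /
#'   "excluded".
#' @export
speciesConservation <- function(ref, aligned) {
  stopifnot(grepl("^CA[ACGT][ACGT]TG$", toupper(ref)))
  out <- vapply(aligned, function(s) {
    if (is.na(s)) return("excluded")
    s <- toupper(s)
    if (grepl("-", s, fixed = TRUE)) return("excluded")
    if (identical(s, toupper(ref))) "conserved" else "diverged"
  }, "")
  names(out) <- names(aligned)
  out
}

#' Phylostratigraphic depth of a motif
#'
#' Clades are ordered shallow to deep (placental < marsupial < monotreme <
#' non-mammal).  The depth is the deepest clade whose conservation threshold
#' AND all shallower thresholds are met (cumulative gating); "none" if the
#' placental threshold already fails.  Excluded species do not count toward
#' the conserved tally; the required count is absolute.
#'
#' @param status Named character vector from [speciesConservation].
#' @param clade Named character vector: species -> clade.
#' @param scheme Clade scheme `data.frame` (default [cladeScheme]).
#' @return One of "none", "placental", "marsupial", "monotreme",
#'   "non_mammal".
#' @export
assignPhylostratum <- function(status, clade, scheme = cladeScheme()) {
  depth <- "none"
  for (i in seq_len(nrow(scheme))) {
    cl <- scheme$clade[i]
    sp <- names(clade)[clade == cl]
    n_cons <- sum(status[sp] == "conserved", na.rm = TRUE)
    if (n_cons >= scheme$required[i]) depth <- cl else break
  }
  depth
}

#' Phylostratum depths for a table of motifs
#'
#' @param blocks Long `data.frame`: `motif_id`, `species`, `clade`,
#'   `aligned`, plus per-motif `ref` (reference hexamer; may repeat).
#' @param scheme Clade scheme (default [cladeScheme]).
#' @return `data.frame`: `motif_id`, `depth`.
#' @export
phylostratumTable <- function(blocks, scheme = cladeScheme()) {
  ids <- unique(blocks$motif_id)
  depth <- vapply(ids, function(id) {
    b <- blocks[blocks$motif_id == id, ]
    st <- speciesConservation(b$ref[1L],
                              setNames(b$aligned, b$species))
    assignPhylostratum(st, setNames(b$clade, b$species), scheme)
  }, "")
  data.frame(motif_id = ids, depth = depth, stringsAsFactors = FALSE)
}
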