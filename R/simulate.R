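## Seeded generators for every input the pipeline consumes, with known
## ground truth.  Each generator is a pure function of (parameters, seed);
## truth tables are returned alongside the artifacts and are never read by
## the analysis operations.

BASES <- c("A", "C", "G", "T")

.randomSeqChar <- function(n, gc = 0.42) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample(BASES, n, replace = TRUE, prob = p)
}

## all CANNTG matches in a character vector of single bases
.eboxStartsIn <- function(chars) {
  s <- paste(chars, collapse = "")
  m <- gregexpr("(?=CA[ACGT][ACGT]TG)", s, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Synthetic genome with summit-enriched planted E-boxes
#'
#' Generates one contig per peak (summit at the centre) of random background
#' sequence at the stated GC content, then plants E-boxes of chosen classes
#' at Poisson rates: one per-bp rate in the near-summit window, another in
#' the distal window.  Planting rejects placements that create unintended
#' E-boxes within +-8 bp of the planted hexamer (flanking background is
#' redrawn), so planted densities stay interpretable as truth.  Optionally a
#' fixed-gap E-box pair is planted near the summit of a fraction of peaks.
#'
#' @param n_peaks Number of peaks/contigs.
#' @param peak_width Contig and peak width in bp (study value 1500).
#' @param density_near,density_distal Named per-bp planting rates by class
#'   label (e.g. `c("CAT-CAT" = 0.03)`).
#' @param near_halfwidth Near window half-width (bp) for planting.
#' @param distal_range Distal |d| planting window (bp).
#' @param gc Background GC content.
#' @param paired_gap If non-NULL, plant an E-box pair with this many
#'   intervening nucleotides (study spacing 6) near the summit of
#'   `paired_fraction` of the peaks.
#' @param paired_class Class of planted pair members.
#' @param paired_fraction Fraction of peaks receiving a pair.
#' @param seed Random seed.
#' @return List: `sequences` (`DNAStringSet`), `peaks` (`GRanges` with
#'   `summit`), `truth` (`data.frame`: contig, class, start, offset,
#'   paired).
#' @export
simEBoxGenome <- function(n_peaks = 200L, peak_width = 1500L,
                          density_near = c("CAT-CAT" = 0.03),
                          density_distal = c("CAT-CAT" = 0.01),
                          near_halfwidth = 50L, distal_range = c(250L, 750L),
                          gc = 0.42, paired_gap = NULL,
                          paired_class = "CAT-CAT", paired_fraction = 0.5,
                          seed = 1L) {
  stopifnot(all(density_near >= 0), all(density_distal >= 0))
  set.seed(seed)
  cls <- eboxClasses()
  reps <- setNames(strsplit(cls$representatives, ",", fixed = TRUE), cls$label)
  summit <- as.integer(peak_width / 2)
  classes <- union(names(density_near), names(density_distal))
  stopifnot(all(classes %in% cls$label))
  seqs <- vector("list", n_peaks)
  truth <- list()
  min_sep <- 7L   # planted hexamer starts at least this far apart
  for (pk in seq_len(n_peaks)) {
    chars <- .randomSeqChar(peak_width, gc)
    planted <- integer(0)   # starts of motifs already placed in this peak
    ## write hexamers at `pos`, then redraw surrounding background until the
    ## +-8 bp neighbourhood contains no unintended E-box
    tryPlace <- function(pos, hexes) {
      pos <- as.integer(pos)
      if (any(pos < 1L | pos + 5L > peak_width)) return(FALSE)
      if (length(planted) &&
          min(abs(outer(pos, planted, "-"))) < min_sep) return(FALSE)
      if (length(pos) > 1L && min(diff(sort(pos))) < min_sep) return(FALSE)
      lo <- max(1L, min(pos) - 8L); hi <- min(peak_width, max(pos) + 13L)
      old <- chars[lo:hi]
      for (k in seq_along(pos))
        chars[pos[k]:(pos[k] + 5L)] <<- strsplit(hexes[k], "")[[1]]
      ## previously planted motifs fully inside the scan window must be
      ## re-found; ones merely overlapping it keep their bases fixed
      inside <- planted[planted >= lo & planted + 5L <= hi]
      overlapping <- planted[planted + 5L >= lo & planted <= hi]
      expect <- sort(c(pos, inside))
      core <- unlist(lapply(c(pos, overlapping), function(p) p:(p + 5L)))
      core <- core[core >= lo & core <= hi]
      for (rtry in seq_len(50L)) {
        starts <- .eboxStartsIn(chars[lo:hi]) + lo - 1L
        if (identical(sort(starts), expect)) {
          planted <<- c(planted, pos)
          return(TRUE)
        }
        flk <- setdiff(lo:hi, core)
        chars[flk] <<- .randomSeqChar(length(flk), gc)
      }
      chars[lo:hi] <<- old
      FALSE
    }
    plant <- function(class, pos_pool, n, paired = FALSE) {
      for (k in seq_len(n)) {
        pool <- pos_pool
        repeat {
          if (length(planted))
            pool <- pool[vapply(pool, function(p)
              min(abs(p - planted)) >= min_sep, TRUE)]
          if (length(pool) == 0L)
            stop("planting density too high to satisfy the rejection rule ",
                 "(no feasible position for motif ", k, " of ", n,
                 " in one window)")
          p <- if (length(pool) == 1L) pool else sample(pool, 1L)
          if (tryPlace(p, sample(reps[[class]], 1L))) {
            truth[[length(truth) + 1L]] <<- data.frame(
              contig = paste0("peak_", pk), class = class, start = p,
              offset = p + 2L - summit, paired = paired)
            break
          }
          pool <- setdiff(pool, p)
        }
      }
      n
    }
    near_pool <- (summit - near_halfwidth):(summit + near_halfwidth - 6L)
    distal_pool <- c((summit - distal_range[2] + 3L):(summit - distal_range[1] - 3L),
                     (summit + distal_range[1] - 2L):(summit + distal_range[2] - 4L))
    distal_pool <- distal_pool[distal_pool >= 1L &
                                 distal_pool <= peak_width - 5L]
    if (!is.null(paired_gap) && runif(1) < paired_fraction) {
      for (try in seq_len(200L)) {
        p1 <- sample(near_pool, 1L)
        p2 <- p1 + 6L + paired_gap
        if (!tryPlace(c(p1, p2), sample(reps[[paired_class]], 2L,
                                        replace = TRUE))) next
        for (p in c(p1, p2))
          truth[[length(truth) + 1L]] <- data.frame(
            contig = paste0("peak_", pk), class = paired_class, start = p,
            offset = p + 2L - summit, paired = TRUE)
        break
      }
    }
    for (class in classes) {
      dn <- if (class %in% names(density_near)) density_near[[class]] else 0
      dd <- if (class %in% names(density_distal)) density_distal[[class]] else 0
      n_near <- rpois(1L, dn * 2 * near_halfwidth)
      n_distal <- rpois(1L, dd * 2 * diff(distal_range))
      plant(class, near_pool, n_near)
      plant(class, distal_pool, n_distal)
    }
    seqs[[pk]] <- paste(chars, collapse = "")
  }
  sequences <- DNAStringSet(unlist(seqs))
  names(sequences) <- paste0("peak_", seq_len(n_peaks))
  peaks <- GRanges(names(sequences), IRanges(1L, peak_width),
                   summit = rep(summit, n_peaks))
  peaks$name <- names(sequences)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(contig = character(0), class = character(0),
               start = integer(0), offset = integer(0), paired = logical(0))
  list(sequences = sequences, peaks = peaks, truth = truth)
}

#' Synthetic pseudobulk accessibility with planted trajectories
#'
#' Region signals are `baseline + amplitude * template + noise` on the log2
#' scale, exponentiated and rounded to counts.  Templates are drawn from the
#' block-aligned single-run family of the layout; invariant regions have
#' amplitude 0.
#'
#' @param layout Named integer vector: pseudobulks per cell type, in axis
#'   order (study layout `c(NSC=8, IPC=5, PN1=7, PN2=8, PN3=2)`).
#' @param n_regions Named counts of regions per trajectory group, e.g.
#'   `c(invariant = 500, falling = 500, transient = 500, neuronal = 500)`.
#' @param amplitude Open-minus-closed signal difference (log2 units).
#' @param noise_sd Gaussian noise sd (log2 units).
#' @param baseline Closed-state log2 signal.
#' @param seed Random seed.
#' @return List: `pseudobulk` (a [PseudobulkMatrix-class] of counts),
#'   `truth` (`data.frame`: region, group, template).
#' @export
simPseudobulk <- function(layout = c(NSC = 8L, IPC = 5L, PN1 = 7L,
                                     PN2 = 8L, PN3 = 2L),
                          n_regions = c(invariant = 500L, falling = 500L,
                                        transient = 500L, neuronal = 500L),
                          amplitude = 4, noise_sd = 1, baseline = 5,
                          seed = 1L) {
  stopifnot(noise_sd >= 0)
  set.seed(seed)
  cell_type <- rep(names(layout), layout)
  templates <- buildTemplates(cell_type)
  tm <- templateMatrix(templates)
  n_samples <- length(cell_type)
  rows <- list(); truth <- list()
  for (grp in names(n_regions)) {
    n <- n_regions[[grp]]
    if (n == 0L) next
    if (grp == "invariant") {
      sig <- matrix(baseline, n, n_samples)
      tnames <- rep(NA_character_, n)
    } else {
      pool <- which(templates$group == grp)
      pick <- sample(pool, n, replace = TRUE)
      sig <- baseline + amplitude * tm[pick, , drop = FALSE]
      tnames <- templates$name[pick]
    }
    sig <- sig + matrix(rnorm(n * n_samples, sd = noise_sd), n, n_samples)
    rows[[grp]] <- sig
    truth[[grp]] <- data.frame(group = grp, template = tnames)
  }
  sig <- do.call(rbind, rows)
  counts <- matrix(as.numeric(round(2^sig)), nrow(sig), ncol(sig))
  rownames(counts) <- paste0("region_", seq_len(nrow(counts)))
  truth <- do.call(rbind, truth)
  truth <- data.frame(region = rownames(counts), truth, row.names = NULL)
  pb <- PseudobulkMatrix(counts, cell_type = cell_type, kind = "counts")
  list(pseudobulk = pb, truth = truth)
}

#' Synthetic cells with expression-coupled accessibility
#'
#' Per-cell TF expression is standard normal; each region's accessibility is
#' `r * expression + sqrt(1 - r^2) * sqrt(group_size) * noise`, so that the
#' Pearson correlation measured on expression-sorted pseudobulk groups of
#' `group_size` cells targets `target_r` (cell-level noise shrinks by
#' `sqrt(group_size)` under group averaging; an unscaled construction would
#' drive all group-level correlations toward 1).
#'
#' @param n_cells Number of cells.
#' @param target_r Per-region target correlations (vector).
#' @param group_size Pseudobulk group size the target refers to (study
#'   value 50).
#' @param seed Random seed.
#' @return List: `expression` (per cell), `access` (regions x cells),
#'   `truth` (`data.frame`: region, target_r).
#' @export
simCoupledCells <- function(n_cells = 2000L, target_r = c(1, 0.6, 0),
                            group_size = 50L, seed = 1L) {
  set.seed(seed)
  expr <- rnorm(n_cells)
  access <- t(vapply(target_r, function(r) {
    r * expr + sqrt(pmax(0, 1 - r^2)) * sqrt(group_size) * rnorm(n_cells)
  }, numeric(n_cells)))
  rownames(access) <- paste0("region_", seq_along(target_r))
  list(expression = expr, access = access,
       truth = data.frame(region = rownames(access), target_r = target_r))
}

#' Synthetic HT-SELEX rounds with affinity-driven selection
#'
#' Round 1 is uniform random fixed-length reads; each later round resamples
#' the previous round with replacement, a read's odds multiplied by
#' `retention_odds` for every contained representative hexamer of a
#' positive-affinity class (exponent scaled by the class affinity).
#'
#' @param n_reads Reads per round.
#' @param read_len Read length (bp).
#' @param n_rounds Number of rounds (study value 4).
#' @param affinity Named affinities by class label; 0/absent = neutral.
#' @param retention_odds Odds multiplier per contained high-affinity
#'   hexamer.
#' @param seed Random seed.
#' @return List: `rounds` (a [SelexRounds-class]), `truth` (`data.frame`:
#'   class, affinity, retention_odds).
#' @export
simSelex <- function(n_reads = 50000L, read_len = 20L, n_rounds = 4L,
                     affinity = c("CAT-CAT" = 1), retention_odds = 3,
                     seed = 1L) {
  set.seed(seed)
  cls <- eboxClasses()
  reps <- setNames(strsplit(cls$representatives, ",", fixed = TRUE), cls$label)
  mk_reads <- function(n) {
    m <- matrix(sample(BASES, n * read_len, replace = TRUE), n, read_len)
    DNAStringSet(apply(m, 1, paste, collapse = ""))
  }
  weightOf <- function(reads) {
    lw <- rep(0, length(reads))
    for (cl in names(affinity)) {
      if (affinity[[cl]] == 0) next
      cnt <- rep(0L, length(reads))
      for (p in reps[[cl]])
        cnt <- cnt + vcountPattern(p, reads, fixed = TRUE)
      lw <- lw + affinity[[cl]] * cnt * log(retention_odds)
    }
    exp(lw)
  }
  rounds <- vector("list", n_rounds)
  rounds[[1L]] <- mk_reads(n_reads)
  for (r in seq_len(n_rounds - 1L)) {
    w <- weightOf(rounds[[r]])
    idx <- sample.int(length(w), n_reads, replace = TRUE, prob = w)
    rounds[[r + 1L]] <- rounds[[r]][idx]
  }
  aff <- setNames(rep(0, nrow(cls)), cls$label)
  aff[names(affinity)] <- affinity
  list(rounds = SelexRounds(rounds),
       truth = data.frame(class = names(aff), affinity = as.numeric(aff),
                          retention_odds = retention_odds))
}

#' Synthetic variants and alignments with summit-graded constraint
#'
#' Builds E-box sites split between PSS (|d| <= 50) and NSS (200-400 bp)
#' windows, then draws: per-site mouse-rat substitution counts at
#' `div_rate` per base, scaled by `pss_constraint` for PSS sites; per-site
#' polymorphic SNVs likewise at `poly_rate`, with minor allele frequencies
#' from a low-frequency-skewed distribution; occasional alignment indels to
#' exercise the exclusion rules; and per-species alignment strings at
#' clade-scaled rates for a subset of motifs.
#'
#' @param n_sites Total number of motifs (half PSS, half NSS).
#' @param classes Class labels to cycle sites over.
#' @param div_rate Neutral substitution probability per base (outgroup).
#' @param poly_rate Neutral polymorphism rate per base.
#' @param pss_constraint Relative rate at PSS (1 = neutral; < 1 =
#'   constrained).  A named vector applies per-class constraints, leaving
#'   unnamed classes neutral.
#' @param indel_prob Probability a site's outgroup alignment spans an indel.
#' @param clade_rates Named per-base substitution rates per clade for the
#'   multi-species blocks.
#' @param n_block_motifs Motifs receiving a multi-species block.
#' @param seed Random seed.
#' @return List: `sites` (`GRanges` with `ebox_class`, `summit_distance`,
#'   `ref`), `variants` (`data.frame`), `outgroup` (`data.frame`: motif_id,
#'   ref_seq, outgroup_seq), `blocks` (long `data.frame`), `truth`.
#' @export
simConservation <- function(n_sites = 10000L,
                            classes = c("CAT-CAT", "CAG-CAG"),
                            div_rate = 0.05, poly_rate = 0.05,
                            pss_constraint = 1, indel_prob = 0.01,
                            clade_rates = c(placental = 0.03,
                                            marsupial = 0.08,
                                            monotreme = 0.12,
                                            non_mammal = 0.2),
                            n_block_motifs = 200L, seed = 1L) {
  set.seed(seed)
  cls <- eboxClasses()
  reps <- setNames(strsplit(cls$representatives, ",", fixed = TRUE), cls$label)
  class_of <- rep(classes, each = ceiling(n_sites / length(classes)))[
    seq_len(n_sites)]
  is_pss <- rep(c(TRUE, FALSE), length.out = n_sites)  # half PSS per class
  d <- ifelse(is_pss, sample(-50:50, n_sites, replace = TRUE),
              sample(c(-400:-200, 200:400), n_sites, replace = TRUE))
  ref <- unname(vapply(class_of, function(cl) sample(reps[[cl]], 1L), ""))
  start <- seq(1L, by = 100L, length.out = n_sites)
  sites <- GRanges("chrS", IRanges(start, width = 6L),
                   ebox_class = class_of, summit_distance = as.integer(d),
                   ref = ref)
  cons_of <- if (is.null(names(pss_constraint))) {
    rep(pss_constraint[1], n_sites)   # same constraint for every class
  } else {                            # per-class constraint, others neutral
    ifelse(class_of %in% names(pss_constraint),
           unname(pss_constraint[class_of]), 1)
  }
  factor_of <- ifelse(is_pss, cons_of, 1)
  ## polymorphisms: per-base Bernoulli; MAF skewed low (many below 0.05)
  n_poly <- rbinom(n_sites, 6L, pmin(1, poly_rate * factor_of))
  v_site <- rep(seq_len(n_sites), n_poly)
  v_off <- unlist(lapply(n_poly, function(k) sample(0:5, k)))
  variants <- data.frame(
    contig = "chrS",
    position = start[v_site] + v_off,
    ref = substring(ref[v_site], v_off + 1L, v_off + 1L),
    alt = NA_character_,
    maf = 0.5 * runif(length(v_site))^2)
  variants$alt <- unname(vapply(variants$ref, function(b)
    sample(setdiff(BASES, b), 1L), ""))
  ## outgroup pairwise alignment
  mutate <- function(hex, p) {
    ch <- strsplit(hex, "")[[1]]
    hit <- runif(6L) < p
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(BASES, b), 1L), "")
    paste(ch, collapse = "")
  }
  outg <- mapply(mutate, ref, pmin(1, div_rate * factor_of))
  gap <- runif(n_sites) < indel_prob
  if (any(gap))
    outg[gap] <- vapply(outg[gap], function(s) {
      i <- sample(1:6, 1L)
      substr(s, i, i) <- "-"
      s
    }, "")
  outgroup <- data.frame(motif_id = seq_len(n_sites), ref_seq = ref,
                         outgroup_seq = unname(outg))
  ## multi-species blocks over the clade scheme
  scheme <- cladeScheme()
  species <- unlist(lapply(seq_len(nrow(scheme)), function(i)
    paste0(scheme$clade[i], "_", seq_len(scheme$total[i]))))
  clade <- rep(scheme$clade, scheme$total)
  blk_ids <- head(seq_len(n_sites), n_block_motifs)
  blocks <- do.call(rbind, lapply(blk_ids, function(id) {
    al <- mapply(function(sp, cl)
      mutate(ref[id], pmin(1, clade_rates[[cl]] * factor_of[id])),
      species, clade)
    data.frame(motif_id = id, species = species, clade = clade,
               aligned = unname(al), ref = ref[id])
  }))
  truth <- data.frame(motif_id = seq_len(n_sites), class = class_of,
                      pss = is_pss, constraint = factor_of)
  list(sites = sites, variants = variants, outgroup = outgroup,
       blocks = blocks, truth = truth)
}

#' Synthetic methylation tracks with a stage-specific dip at chosen motifs
#'
#' Produces two piecewise-constant %CpG methylation tracks (10-bp steps,
#' values clamped to [0, 100]) covering windows around the given sites: both
#' stages sit at `baseline_pct`, and the dip stage drops by `dip_pct` within
#' `dip_halfwidth` bp of the midpoints of sites in `dip_classes`.
#'
#' @param sites E-box `GRanges` with `ebox_class`.
#' @param baseline_pct Baseline methylation (default 80).
#' @param dip_pct Depth of the demethylation dip (percentage points).
#' @param dip_halfwidth Dip half-width around site midpoints (bp).
#' @param dip_classes Classes receiving the dip.
#' @param dip_stage Which stage carries the dip ("b" = the PN-like track).
#' @param flank Track coverage around each site midpoint.
#' @param noise_sd Gaussian noise per step (same draw shared by both stages,
#'   so identical-track deltas stay exactly 0 when `dip_pct = 0`).
#' @param seed Random seed.
#' @return List: `track_a`, `track_b` (`GRanges` with `score`), `truth`.
#' @export
simMethylation <- function(sites, baseline_pct = 80, dip_pct = 60,
                           dip_halfwidth = 100, dip_classes = "CAT-CAT",
                           dip_stage = c("b", "a"), flank = 1500,
                           noise_sd = 2, seed = 1L) {
  dip_stage <- match.arg(dip_stage)
  set.seed(seed)
  step <- 10L
  mid <- floor((start(sites) + end(sites)) / 2)
  win_start <- pmax(1L, (mid - flank) %/% step * step + 1L)
  win_end <- (mid + flank) %/% step * step
  segs <- list()
  for (i in seq_along(sites)) {
    st <- seq(win_start[i], win_end[i] - step + 1L, by = step)
    segs[[i]] <- data.frame(contig = as.character(seqnames(sites)[i]),
                            start = st, site = i)
  }
  segs <- do.call(rbind, segs)
  ## collapse duplicate steps from overlapping windows
  key <- paste(segs$contig, segs$start)
  segs <- segs[!duplicated(key), ]
  base <- pmin(100, pmax(0, baseline_pct + rnorm(nrow(segs), sd = noise_sd)))
  gr <- GRanges(segs$contig, IRanges(segs$start, width = step), score = base)
  dipped_sites <- sites[sites$ebox_class %in% dip_classes]
  dip_val <- base
  if (length(dipped_sites) && dip_pct != 0) {
    dmid <- floor((start(dipped_sites) + end(dipped_sites)) / 2)
    dwin <- GRanges(seqnames(dipped_sites),
                    IRanges(dmid - dip_halfwidth, dmid + dip_halfwidth))
    hit <- overlapsAny(gr, dwin)
    dip_val[hit] <- pmax(0, dip_val[hit] - dip_pct)
  }
  gr_dip <- gr
  gr_dip$score <- dip_val
  track_a <- if (dip_stage == "a") gr_dip else gr
  track_b <- if (dip_stage == "b") gr_dip else gr
  list(track_a = track_a, track_b = track_b,
       truth = data.frame(dip_classes = paste(dip_classes, collapse = ","),
                          dip_pct = dip_pct, dip_stage = dip_stage))
}
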