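test_that("centrality is the near/distal per-bp density fold", {
  # 10 near motifs over 100 near bp vs 5 distal over 500 distal bp -> 10.0
  sites <- sitesGR(rep("CAT-CAT", 15), c(rep(0, 10), rep(300, 5)))
  cen <- motifCentrality(sites, n_peaks = 1, near_halfwidth = 50,
                         distal_start = 250, distal_end = 500)
  row <- cen[cen$ebox_class == "CAT-CAT", ]
  expect_equal(row$near_count, 10L)
  expect_equal(row$distal_count, 5L)
  expect_equal(row$centrality, (10 / 100) / (5 / 500))
  # no distal motifs -> missing, not infinite
  s2 <- sitesGR("CAG-CAG", 0)
  cen2 <- motifCentrality(s2, n_peaks = 1)
  expect_true(is.na(cen2$centrality[cen2$ebox_class == "CAG-CAG"]))
  expect_true(all(is.finite(cen$centrality) | is.na(cen$centrality)))
  # conservation: near counts sum to all sites in near windows
  expect_equal(sum(cen$near_count), 10L)
})

test_that("uniform planting yields centrality near 1, 3x planting near 3", {
  g3 <- simEBoxGenome(n_peaks = 120, density_near = c("CAT-CAT" = 0.03),
                      density_distal = c("CAT-CAT" = 0.01), seed = 301)
  s3 <- annotateSummitDistance(scanEBoxSet(g3$sequences), g3$peaks)
  c3 <- motifCentrality(s3)
  expect_gt(c3$centrality[c3$ebox_class == "CAT-CAT"], 2.4)
  expect_lt(c3$centrality[c3$ebox_class == "CAT-CAT"], 3.6)
  g1 <- simEBoxGenome(n_peaks = 120, density_near = c("CAT-CAT" = 0.02),
                      density_distal = c("CAT-CAT" = 0.02), seed = 302)
  s1 <- annotateSummitDistance(scanEBoxSet(g1$sequences), g1$peaks)
  c1 <- motifCentrality(s1)
  expect_gt(c1$centrality[c1$ebox_class == "CAT-CAT"], 0.85)
  expect_lt(c1$centrality[c1$ebox_class == "CAT-CAT"], 1.15)
})

test_that("motifs per peak and distal fold handle empty windows", {
  sites <- sitesGR(rep("CAT-CAT", 2), c(10, -50))
  mp <- motifsPerPeak(sites, n_peaks = 1)
  expect_equal(mp$mean_per_peak[mp$ebox_class == "CAT-CAT"], 2)
  expect_equal(mp$mean_per_peak[mp$ebox_class == "CAG-CAG"], 0)
  expect_true(is.na(mp$fold[mp$ebox_class == "CAT-CAT"]))  # no distal sites
  # equal near/distal per-bp density -> fold near 1
  d <- c(rep(50, 40), rep(400, 220))   # 40/200bp vs 220/1100bp = 0.2 each
  s2 <- sitesGR(rep("CAT-CAT", 260), d)
  mp2 <- motifsPerPeak(s2, n_peaks = 1, near_halfwidth = 100,
                       distal_threshold = 200, distal_end = 750)
  expect_equal(mp2$fold[mp2$ebox_class == "CAT-CAT"], 1)
})

test_that("flank bias stratifies upstream dinucleotides by half-site", {
  # all sites in a GCCATATGGC context: both halves are CAT, both flanks GC
  sites <- scanEBoxSet(DNAStringSet(setNames(rep("GCCATATGGC", 4),
                                             paste0("s", 1:4))))
  sites$summit_distance <- c(0L, 0L, 300L, 300L)
  fb <- flankBias(sites, near_halfwidth = 100, distal_threshold = 200)
  cat_gc <- fb[fb$half_site == "CAT" & fb$dinucleotide == "GC", ]
  expect_equal(cat_gc$prop_near, 1)
  expect_equal(cat_gc$prop_distal, 1)
  expect_equal(cat_gc$fold, 1)
  # proportions per half-site sum to 1 (where the half-site occurs)
  sums <- tapply(fb$prop_near, fb$half_site, sum)
  expect_equal(unname(sums[["CAT"]]), 1)
  # identical near and distal distributions give folds of 1
  expect_true(all(fb$fold[!is.na(fb$fold)] == 1))
})

test_that("pair spacing counts intervening nucleotides within peaks", {
  gr <- GRanges("c", IRanges(c(11, 23), width = 6))   # 0-based starts 10, 22
  gr$ebox_class <- "CAT-CAT"
  gr$peak_id <- 1L
  sp <- pairSpacing(gr)
  expect_equal(sp$count[sp$gap == 6], 1L)
  expect_equal(sum(sp$count), 1L)
  # a single site contributes nothing
  sp1 <- pairSpacing(gr[1])
  expect_equal(sum(sp1$count), 0L)
  # overlapping hexamers land in the overlap bucket, not the proportions
  ov <- GRanges("c", IRanges(c(11, 14), width = 6))
  ov$ebox_class <- "CAT-CAT"; ov$peak_id <- 1L
  spo <- pairSpacing(ov)
  expect_equal(unique(spo$n_overlap), 1L)
  expect_equal(sum(spo$count), 0L)
  # all ordered pairs are counted, not only adjacent ones
  tri <- GRanges("c", IRanges(c(1, 13, 25), width = 6))
  tri$ebox_class <- "CAT-CAT"; tri$peak_id <- 1L
  spt <- pairSpacing(tri)
  expect_equal(sum(spt$count), 3L)
  expect_equal(spt$count[spt$gap == 6], 2L)
  expect_equal(spt$count[spt$gap == 18], 1L)
})

test_that("planted fixed-gap pairs dominate the spacing distribution", {
  g <- simEBoxGenome(n_peaks = 80, density_near = c("CAT-CAT" = 0.015),
                     density_distal = c("CAT-CAT" = 0.005),
                     paired_gap = 6, seed = 303)
  s <- annotateSummitDistance(scanEBoxSet(g$sequences), g$peaks)
  sp <- pairSpacing(s)
  expect_equal(sp$gap[which.max(sp$proportion)], 6)
})

test_that("score-binned enrichment applies the window rule and scaling", {
  # 0.4-of-length window on a 1000 bp peak is 400 bp centred on the summit
  peaks <- peaksGR(rep(1, 4), rep(1000, 4), rep(500, 4), contig = "c")
  inside <- GRanges("c", IRanges(350, width = 6))   # within [300, 700]
  outside <- GRanges("c", IRanges(200, width = 6))  # outside the 400bp window
  sites <- c(inside, outside)
  sites$ebox_class <- "CAT-CAT"
  m <- scoreBinEnrichment(peaks, score = 1:4, sites, n_bins = 2L,
                          window = "fraction", fraction = 0.4)
  # the single in-window site counts once per covering peak: 1 per peak
  expect_equal(unname(m["CAT-CAT", ]), c(1, 1))
  mfix <- scoreBinEnrichment(peaks, 1:4, sites, n_bins = 2L,
                             window = "fixed", halfwidth = 300)
  expect_gt(sum(mfix["CAT-CAT", ]), sum(m["CAT-CAT", ]))
  # identical bins scale to all zeros (sd-0 guard)
  msc <- scoreBinEnrichment(peaks, 1:4, sites, n_bins = 2L, scale_rows = TRUE)
  expect_true(all(msc == 0 | abs(msc) > 0))
  flat <- scoreBinEnrichment(peaks, 1:4, inside_only <- {
    x <- c(inside, inside); x$ebox_class <- "CAG-CAG"; x
  }, n_bins = 2L, scale_rows = TRUE)
  expect_true(all(flat["CAG-CAG", ] == 0))
})

test_that("grammar statistics are invariant under genome-wide strand flip", {
  g <- simEBoxGenome(n_peaks = 30, density_near = c("CAT-CAT" = 0.02,
                                                    "CAT-CAG" = 0.02),
                     density_distal = c("CAT-CAT" = 0.01, "CAT-CAG" = 0.01),
                     seed = 305)
  fwd <- annotateSummitDistance(scanEBoxSet(g$sequences), g$peaks)
  flipped <- Biostrings::reverseComplement(g$sequences)
  # flipping reverses coordinates; summits mirror within each contig
  w <- width(g$sequences)
  peaks_f <- g$peaks
  peaks_f$summit <- w - g$peaks$summit + 1L
  rev <- annotateSummitDistance(scanEBoxSet(flipped), peaks_f)
  # same sites, same classes on both strands
  expect_equal(sort(fwd$ebox_class), sort(rev$ebox_class))
  cf <- motifCentrality(fwd)
  cr <- motifCentrality(rev)
  # window membership can differ by the 1 bp midpoint asymmetry of an
  # even-width motif; the statistics must agree closely
  for (k in which(cf$near_count > 20))
    expect_lt(abs(cf$centrality[k] - cr$centrality[k]) /
                cf$centrality[k], 0.15)
})
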