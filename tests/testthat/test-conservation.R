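test_that("polymorphism counting applies the inclusive MAF rule", {
  sites <- GRanges("chr1", IRanges(101, width = 6))  # hexamer 101..106
  vars <- data.frame(contig = "chr1",
                     position = c(103, 104, 107, 105),
                     ref = c("A", "C", "G", "AT"),
                     alt = c("G", "T", "A", "A"),
                     maf = c(0.05, 0.04, 0.30, 0.40))
  # MAF 0.05 counted (inclusive), 0.04 not; position 107 outside the
  # half-open hexamer; indel row dropped
  expect_equal(countPolymorphisms(sites, vars), 1L)
  expect_equal(countPolymorphisms(sites, vars, maf_min = 0.01), 2L)
})

test_that("substitution counting excludes indel-spanning motifs", {
  res <- countSubstitutions(
    c("CAGATG", "CAGATG", "CAGATG", "CAGATG", "CAGATG"),
    c("CAGGTG", "CAGATG", "CAG-TG", NA, "CTGGTG"))
  expect_equal(res$substitutions, c(1L, 0L, NA, NA, 2L))
  expect_equal(res$excluded, c("no", "no", "indel", "uncovered", "no"))
})

test_that("distance-binned variation summarizes counts by |d|", {
  d <- c(10, 60, 110, 460)
  cnt <- c(0, 1, 2, 3)
  b <- distanceBinnedVariation(d, cnt, bin_width = 50, max_distance = 500)
  expect_equal(nrow(b), 10L)
  expect_equal(b$mean[1], 0)
  expect_equal(b$mean[2], 1)
  expect_equal(b$mean[10], 3)
  expect_true(all(is.na(b$mean[b$n == 0])))
  # one bin swallows everything when bin_width >= max_distance
  b1 <- distanceBinnedVariation(d, cnt, bin_width = 500, max_distance = 500)
  expect_equal(nrow(b1), 1L)
  expect_equal(b1$mean, mean(cnt))
})

test_that("PSS/NSS ratios follow the printed windows and rates", {
  # PSS rate 0.02/motif vs NSS 0.08/motif -> ratio 0.25
  cls <- rep("CAT-CAT", 200)
  d <- c(rep(0, 100), rep(300, 100))
  poly <- c(rep(c(1, rep(0, 49)), 2), rep(c(1, 1, 1, 1, rep(0, 46)), 2))
  r <- pssNssRatios(cls, d, poly_counts = poly)
  row <- r[r$ebox_class == "CAT-CAT", ]
  expect_equal(row$pPSS, 0.02)
  expect_equal(row$pNSS, 0.08)
  expect_equal(row$p_ratio, 0.25)
  # identical rates give ratio 1
  req <- pssNssRatios(cls, d, poly_counts = rep(1, 200))
  expect_equal(req$p_ratio[req$ebox_class == "CAT-CAT"], 1)
  # boundaries inclusive: |d| = 50 is PSS; 200 and 400 are NSS
  rb <- pssNssRatios(rep("CAT-CAT", 3), c(50, 200, 400),
                     poly_counts = c(1, 1, 1))
  expect_equal(rb$n_pss[rb$ebox_class == "CAT-CAT"], 1L)
  expect_equal(rb$n_nss[rb$ebox_class == "CAT-CAT"], 2L)
  # a class with no NSS motifs has missing ratios
  rn <- pssNssRatios("CAT-CAT", 0, poly_counts = 1)
  expect_true(is.na(rn$p_ratio[rn$ebox_class == "CAT-CAT"]))
  # totals are conserved across the PSS/NSS partition
  expect_equal(row$pPSS * row$n_pss + row$pNSS * row$n_nss, sum(poly))
})

test_that("MK resampling is seeded and lands constrained classes in the
          purifying quadrant", {
  sim <- simConservation(n_sites = 3000,
                         classes = c("CAT-CAT", "CAG-CAG"),
                         pss_constraint = c("CAT-CAT" = 0.25), seed = 51)
  poly <- countPolymorphisms(sim$sites, sim$variants)
  dv <- countSubstitutions(sim$outgroup$ref_seq, sim$outgroup$outgroup_seq)
  mk <- mkResample(sim$sites$ebox_class, sim$sites$summit_distance,
                   poly, dv$substitutions, n_subsets = 40, seed = 52)
  purifying <- tapply(mk$quadrant == "purifying", mk$ebox_class, mean)
  expect_gte(purifying[["CAT-CAT"]], 0.9)
  expect_lt(purifying[["CAG-CAG"]], 0.9)   # neutral class straddles 1
  # same seed reproduces identical points
  mk2 <- mkResample(sim$sites$ebox_class, sim$sites$summit_distance,
                    poly, dv$substitutions, n_subsets = 40, seed = 52)
  expect_equal(mk, mk2)
  # degenerate all-zero counts give missing ratios
  mk0 <- mkResample(rep("CAT-CAT", 20), rep(c(0, 300), 10),
                    rep(0, 20), rep(0, 20), n_subsets = 3,
                    subset_size = 10, seed = 53)
  expect_true(all(is.na(mk0$p_ratio)))
})

test_that("species conservation statuses follow the zero-substitution rule", {
  st <- speciesConservation("CAGATG", c(rat = "CAGATG", human = "CAGGTG",
                                        frog = "CAG-TG", fish = NA))
  expect_equal(unname(st), c("conserved", "diverged", "excluded", "excluded"))
})

test_that("phylostratum depth uses cumulative clade gating", {
  scheme <- cladeScheme()
  mkStatus <- function(n_pl, n_ma, n_mo, n_nm) {
    clade <- rep(scheme$clade, scheme$total)
    names(clade) <- paste0("sp", seq_along(clade))
    conserved <- c(seq_len(39) <= n_pl, seq_len(3) <= n_ma,
                   seq_len(1) <= n_mo, seq_len(16) <= n_nm)
    status <- ifelse(conserved, "conserved", "diverged")
    names(status) <- names(clade)
    list(status = status, clade = clade)
  }
  a <- mkStatus(25, 0, 0, 0)
  expect_equal(assignPhylostratum(a$status, a$clade), "placental")
  b <- mkStatus(25, 2, 1, 10)
  expect_equal(assignPhylostratum(b$status, b$clade), "non_mammal")
  # deep conservation without the shallow gate is not counted (cumulative)
  c_ <- mkStatus(10, 3, 1, 10)
  expect_equal(assignPhylostratum(c_$status, c_$clade), "none")
  # monotone: adding conserved species never decreases depth
  depths <- c("none", "placental", "marsupial", "monotreme", "non_mammal")
  last <- "none"
  for (n in c(10, 20, 25, 39)) {
    s <- mkStatus(n, 3, 1, 16)
    d <- assignPhylostratum(s$status, s$clade)
    expect_gte(match(d, depths), match(last, depths))
    last <- d
  }
  # excluded species do not count toward the conserved tally
  e <- mkStatus(20, 1, 1, 8)
  e$status[1] <- "excluded"   # drops placental to 19 conserved
  expect_equal(assignPhylostratum(e$status, e$clade), "none")
})

test_that("neutral and constrained simulations recover their ratios", {
  neutral <- sapply(61:63, function(s) {
    sim <- simConservation(n_sites = 4000, pss_constraint = 1, seed = s)
    poly <- countPolymorphisms(sim$sites, sim$variants)
    dv <- countSubstitutions(sim$outgroup$ref_seq, sim$outgroup$outgroup_seq)
    r <- pssNssRatios(sim$sites$ebox_class, sim$sites$summit_distance,
                      poly, dv$substitutions)
    colMeans(r[r$n_pss > 0, c("p_ratio", "d_ratio")])
  })
  expect_lt(abs(mean(neutral["p_ratio", ]) - 1), 0.1)
  expect_lt(abs(mean(neutral["d_ratio", ]) - 1), 0.1)
  sim <- simConservation(n_sites = 6000, pss_constraint = 0.25, seed = 64)
  poly <- countPolymorphisms(sim$sites, sim$variants)
  dv <- countSubstitutions(sim$outgroup$ref_seq, sim$outgroup$outgroup_seq)
  r <- pssNssRatios(sim$sites$ebox_class, sim$sites$summit_distance,
                    poly, dv$substitutions)
  got <- colMeans(r[r$n_pss > 0, c("p_ratio", "d_ratio")])
  expect_lt(abs(got[["p_ratio"]] - 0.25), 0.15)
  expect_lt(abs(got[["d_ratio"]] - 0.25), 0.15)
})
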