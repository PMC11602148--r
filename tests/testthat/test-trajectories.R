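layoutTypes <- function(layout = c(NSC = 8, IPC = 5, PN1 = 7, PN2 = 8, PN3 = 2))
  rep(names(layout), layout)

test_that("pseudobulk aggregation sums pseudotime blocks within cell type", {
  # 8/5/7/8/2 groups of 175 cells -> 30 samples
  layout <- c(NSC = 8, IPC = 5, PN1 = 7, PN2 = 8, PN3 = 2)
  n_cells <- sum(layout) * 175L
  ct <- rep(names(layout), layout * 175L)
  set.seed(1)
  counts <- matrix(rpois(3 * n_cells, 2), nrow = 3)
  pb <- pseudobulkAggregate(counts, ct, pseudotime = seq_len(n_cells),
                            group_size = 175L)
  expect_equal(ncol(pb), 30L)
  expect_equal(unname(table(cellTypes(pb))[names(layout)]),
               unname(layout), ignore_attr = TRUE)
  expect_equal(sum(assay(pb)), sum(counts))
  # 4 identical cells, group size 2 -> each sample is 2x the cell vector
  cc <- matrix(rep(c(1, 3, 5), 4), nrow = 3)
  pb2 <- pseudobulkAggregate(cc, rep("NSC", 4), pseudotime = 1:4,
                             group_size = 2L)
  expect_equal(ncol(pb2), 2L)
  expect_equal(unname(assay(pb2)[, 1]), c(2, 6, 10))
  # all-zero counts stay zero
  pb0 <- pseudobulkAggregate(matrix(0, 2, 4), rep("NSC", 4), 1:4, 2L)
  expect_true(all(assay(pb0) == 0))
  # remainder >= half group size forms its own final group
  pb3 <- pseudobulkAggregate(matrix(1, 1, 5), rep("NSC", 5), 1:5, 3L)
  expect_equal(ncol(pb3), 2L)
  # remainder < half merges into the previous block
  pb4 <- pseudobulkAggregate(matrix(1, 1, 7), rep("NSC", 7), 1:7, 3L)
  expect_equal(ncol(pb4), 2L)
  expect_equal(unname(assay(pb4)[1, ]), c(3, 4))
  # undersized cell type contributes a single group with a warning
  expect_warning(pseudobulkAggregate(matrix(1, 1, 2), rep("NSC", 2), 1:2, 5L),
                 "fewer cells")
})

test_that("log2 CPM matches its closed form and is scale invariant", {
  m <- matrix(c(10, 0), nrow = 2, dimnames = list(NULL, "s1"))
  norm <- log2CPM(m)
  expect_equal(unname(norm[1, 1]), log2(1e6 + 1), tolerance = 1e-12)
  expect_equal(unname(norm[2, 1]), 0)
  m2 <- cbind(s1 = c(5, 15), s2 = c(10, 30))   # s2 = 2 x s1
  n2 <- log2CPM(m2)
  expect_equal(n2[, 1], n2[, 2])
  expect_error(log2CPM(cbind(a = c(0, 0))), "zero column sum")
})

test_that("per-region ANOVA agrees with a closed-form F oracle", {
  g <- factor(rep(c("A", "B", "C"), each = 4))
  set.seed(2)
  v <- c(rnorm(4, 0), rnorm(4, 0), rnorm(4, 3))
  # closed-form one-way F
  gm <- tapply(v, g, mean)
  ssb <- sum(tapply(v, g, length) * (gm - mean(v))^2)
  ssw <- sum((v - gm[g])^2)
  Fref <- (ssb / 2) / (ssw / 9)
  res <- anovaInvariant(matrix(v, nrow = 1), cell_type = as.character(g))
  expect_equal(res$F, Fref, tolerance = 1e-10)
  expect_equal(res$p, pf(Fref, 2, 9, lower.tail = FALSE), tolerance = 1e-10)
  # constant region is invariant by convention
  cst <- anovaInvariant(matrix(5, 1, 12), cell_type = as.character(g))
  expect_true(cst$invariant)
  # strong group separation is dynamic at the 1e-6 rule
  strong <- rep(c(0, 0, 10), each = 4) + rnorm(12, sd = 0.01)
  res2 <- anovaInvariant(matrix(strong, 1), cell_type = as.character(g))
  expect_lt(res2$p, 1e-6)
  expect_false(res2$invariant)
  # shuffling group labels on a dynamic region raises p (permutation oracle)
  set.seed(3)
  perms <- replicate(30, {
    anovaInvariant(matrix(strong, 1), cell_type = sample(as.character(g)))$p
  })
  expect_gt(median(perms), res2$p)
})

test_that("templates are the single-run block-aligned family", {
  ct <- layoutTypes()
  tpl <- buildTemplates(ct)
  tm <- templateMatrix(tpl)
  # every template: one maximal run of 1s, block-aligned; no all-0/all-1
  bounds <- cumsum(rle(ct)$lengths)
  for (i in seq_len(nrow(tm))) {
    v <- tm[i, ]
    runs <- rle(v)
    expect_equal(sum(runs$values == 1L), 1L)
    expect_true(sum(v) > 0 && sum(v) < length(v))
    idx <- which(v == 1L)
    expect_true((min(idx) - 1L) %in% c(0L, bounds))
    expect_true(max(idx) %in% bounds)
  }
  expect_equal(anyDuplicated(tpl$vector), 0L)
  # the study's two printed example vectors are present with their groups
  expect_equal(tpl$group[tpl$vector == "000000001111111111110000000000"],
               "transient")
  expect_equal(tpl$group[tpl$vector == "000000000000000000000000000011"],
               "neuronal")
  # enumeration oracle: contiguous block ranges of K blocks = K(K+1)/2,
  # minus the all-1 full run
  expect_equal(nrow(tpl), 5L * 6L / 2L - 1L)
  expect_equal(table(tpl$group)[["falling"]], 4L)
  expect_equal(table(tpl$group)[["neuronal"]], 4L)
  expect_equal(table(tpl$group)[["transient"]], 6L)
})

test_that("trajectory calls pick the best-correlated template", {
  ct <- layoutTypes()
  tpl <- buildTemplates(ct)
  tm <- templateMatrix(tpl)
  # a region equal to a template recovers it with r = 1
  m <- matrix(as.numeric(tm[3, ]), nrow = 1)
  anv <- data.frame(F = 100, p = 1e-20, invariant = FALSE)
  call <- assignTrajectories(m, tpl, anv)
  expect_equal(call$best_template, tpl$name[3])
  expect_equal(call$pearson_r, 1)
  expect_equal(call$label, tpl$group[3])
  # the complement of a template is matched by the complementary run
  v <- 1 - tm[which(tpl$vector == "000000001111111111110000000000"), ]
  cv <- assignTrajectories(matrix(as.numeric(v), 1), tpl, anv)
  expect_gt(cv$pearson_r, 0)
  expect_true(cv$label != "transient")
  # affine rescaling does not change the call (Pearson property)
  call2 <- assignTrajectories(matrix(5 + 3 * as.numeric(tm[3, ]), 1), tpl, anv)
  expect_equal(call2$best_template, call$best_template)
  # ANOVA-invariant regions and zero-variance vectors are labelled invariant
  anv_inv <- data.frame(F = 1, p = 0.5, invariant = TRUE)
  expect_equal(assignTrajectories(m, tpl, anv_inv)$label, "invariant")
  flat <- assignTrajectories(matrix(2, 1, ncol(tm)), tpl, anv)
  expect_equal(flat$label, "invariant")
})

test_that("noisy planted trajectories are recovered at high rate", {
  sim <- simPseudobulk(n_regions = c(invariant = 100, falling = 100,
                                     transient = 100, neuronal = 100),
                       amplitude = 4, noise_sd = 1, seed = 99)
  calls <- assignTrajectories(log2CPM(sim$pseudobulk))
  dyn <- sim$truth$group != "invariant"
  called_dyn <- calls$label != "invariant"
  # classifier contract: among regions passing the ANOVA gate, the group is
  # almost always right
  expect_gt(mean(calls$label[dyn & called_dyn] ==
                   sim$truth$group[dyn & called_dyn]), 0.95)
  # invariant false-positive rate under the 1e-6 rule
  expect_lt(mean(called_dyn[!dyn]), 0.05)
})

test_that("expression-accessibility correlation over sorted 50-cell groups", {
  set.seed(5)
  expr <- rnorm(400)
  acc <- rbind(expr, -expr, rnorm(400))
  r <- exprAccessCorrelation(expr, acc, group_size = 50L)
  expect_equal(r[1], 1)
  expect_equal(r[2], -1)
  expect_lt(abs(r[3]), 0.9)   # noise row should not correlate strongly
  expect_error(exprAccessCorrelation(rnorm(40), matrix(rnorm(40), 1), 50L),
               "fewer than 2 groups")
  # generator-calibrated targets are recovered at the stated group size
  sim <- simCoupledCells(n_cells = 2000, target_r = c(1, 0.6, 0), seed = 17)
  est <- exprAccessCorrelation(sim$expression, sim$access, group_size = 50L)
  expect_equal(est[1], 1, tolerance = 1e-8)
  expect_lt(abs(est[2] - 0.6), 0.15)
  expect_lt(abs(est[3]), 0.2)
})

test_that("quantile occupancy fractions reconcile with the global rate", {
  set.seed(6)
  regions <- GRanges("c", IRanges(seq(1, by = 1000, length.out = 100),
                                  width = 500))
  score <- seq_len(100)
  bound <- regions[51:100]   # top half bound
  q <- quantileOccupancy(regions, score, list(tf = bound), n_bins = 2L)
  expect_equal(unname(q$fractions[, "tf"]), c(0, 1))
  expect_equal(unname(q$fold["tf"]), Inf)
  # weighted bin fractions equal the global bound fraction
  bound2 <- regions[sample(100, 37)]
  q2 <- quantileOccupancy(regions, score, list(tf = bound2), n_bins = 10L)
  expect_equal(mean(q2$fractions[, "tf"]), 0.37)
})

test_that("cluster accessibility uses the inclusive 3% rule", {
  expect_true(accessibleInCluster(c(rep(1, 3), rep(0, 97))))
  expect_false(accessibleInCluster(c(rep(1, 2), rep(0, 98))))
  expect_false(accessibleInCluster(rep(0, 50)))
  m <- rbind(c(1, rep(0, 99)), rep(1, 100))
  expect_equal(unname(accessibleInCluster(m)), c(FALSE, TRUE))
})
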