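# Simple, batch-aware and supervised feature selectors.

test_that("high_variance ranks features by raw variance", {
  m <- cbind(
    rep(1, 10), # variance 0
    c(rep(0, 5), rep(2, 5)), # variance ~1.1
    c(rep(0, 5), rep(4, 5)) # variance ~4.4
  )
  colnames(m) <- c("f1", "f2", "f3")
  rownames(m) <- sprintf("c%02d", 1:10)
  cm <- CellMatrix(m, batch = rep("b", 10), label = rep("L", 10))
  res <- selectFeatures(cm, "high_variance", n = 2)
  expect_equal(res$features, c("f3", "f2"))
  expect_error(selectFeatures(cm, "high_variance", n = 5), "exceeds")
  expect_equal(length(selectFeatures(cm, "all")$features), 3)
})

test_that("random selection is seeded and has the expected overlap", {
  cm <- randomCellMatrix(30, 1000, seed = 2)
  r1 <- selectFeatures(cm, "random", n = 100, seed = 7)
  r2 <- selectFeatures(cm, "random", n = 100, seed = 7)
  expect_identical(r1$features, r2$features)
  # pairwise Jaccard across seeds ~ n / n_features / (2 - n / n_features)
  jac <- vapply(1:50, function(s) {
    a <- selectFeatures(cm, "random", n = 100, seed = s)$features
    b <- selectFeatures(cm, "random", n = 100, seed = s + 100)$features
    length(intersect(a, b)) / length(union(a, b))
  }, numeric(1))
  # expected intersection 10, union 190 -> ~0.0526
  expect_lt(abs(mean(jac) - 10 / 190), 0.015)
})

test_that("variance-based HVG selectors recover spiked DE genes", {
  # strong spike-in design: DE factors bounded away from 1 (3- to 6-fold)
  cfg <- simConfig(
    nFeatures = 500,
    labelSpec = data.frame(
      name = c("A", "B"), n_cells = c(300, 300),
      de_prob = c(0, 0.1), de_scale = c(0, 0.2), noise_sd = 0
    ),
    batchSpec = data.frame(
      name = c("b1", "b2"), depth_factor = 1,
      n_cells_factor = 1
    ),
    queryBatches = "b2", unseenLabels = character(),
    trajectorySpec = NULL, deLoc = 1.5, batchLoc = 0, batchSd = 0, seed = 31
  )
  ds <- simulateCounts(cfg)
  gt <- provenance(ds)$ground_truth
  # detectable ground-truth DE: a fold change on an expressed gene (a fold
  # change on a near-zero base mean yields no usable counts at this depth)
  detectable <- gt$de_flags[, "B"] & gt$base_means >= 0.5
  spiked <- rownames(gt$de_flags)[detectable]
  ref <- reference(ds)
  n_de <- length(spiked)
  for (method in c("hvg_vst", "hvg_binned_dispersion")) {
    top <- selectFeatures(ref, method, n = 2 * n_de)$features
    recovery <- mean(spiked %in% top)
    expect_gt(recovery, 0.9)
  }
  # the VST ranking concentrates DE genes at the very top
  top_n <- selectFeatures(ref, "hvg_vst", n = n_de)$features
  expect_gt(mean(top_n %in% spiked), 0.8)
})

test_that("batch-aware combination matches per-batch evidence", {
  # identical batches give the same set as pooled selection
  set.seed(5)
  m <- matrix(rpois(60 * 40, 5), 60, 40)
  m[, 1:5] <- m[, 1:5] * rep(c(1L, 6L), each = 30) # strong variance genes
  rownames(m) <- sprintf("c%03d", 1:60)
  colnames(m) <- sprintf("g%03d", 1:40)
  dup <- rbind(m, m)
  rownames(dup) <- sprintf("c%03d", 1:120)
  cm <- CellMatrix(dup,
    batch = rep(c("b1", "b2"), each = 60),
    label = rep("L", 120)
  )
  plain <- selectFeatures(cm, "high_variance", n = 10)
  aware <- selectBatchAware(cm, "high_variance", n = 10)
  expect_setequal(plain$features, aware$features)
  expect_true(aware$batchAware)

  # a feature selected by all batches outranks one selected by a single batch
  counts3 <- matrix(rpois(90 * 6, 2), 90, 6)
  counts3[, 1] <- rpois(90, 2) + rep(c(0L, 9L), times = 45) # everywhere
  counts3[1:30, 2] <- rep(c(0L, 25L), 15) # batch 1 only
  rownames(counts3) <- sprintf("c%03d", 1:90)
  colnames(counts3) <- sprintf("g%d", 1:6)
  cm3 <- CellMatrix(counts3,
    batch = rep(c("x", "y", "z"), each = 30),
    label = rep("L", 90)
  )
  res <- selectBatchAware(cm3, "high_variance", n = 2)
  expect_equal(res$features[1], "g1")
})

test_that("vectorised rank-sum test replicates wilcox.test", {
  set.seed(9)
  x <- matrix(rpois(40 * 8, 3), 40, 8)
  grp <- rep(c(TRUE, FALSE), each = 20)
  mine <- scMapBench:::rankSumTest(x, grp)
  for (j in 1:8) {
    ref <- wilcox.test(x[grp, j], x[!grp, j],
      exact = FALSE, correct = TRUE
    )
    expect_equal(mine$p.value[j], ref$p.value, tolerance = 1e-9)
    expect_equal(mine$statistic[j], unname(ref$statistic), tolerance = 1e-9)
  }
})

test_that("marker cascade applies the expression and p-value filters exactly", {
  # 3 labels x 12 features with controlled expression fractions
  set.seed(1)
  n_per <- 40
  labels <- rep(c("L1", "L2", "L3"), each = n_per)
  n <- length(labels)
  m <- matrix(0L, n, 12)
  colnames(m) <- sprintf("f%02d", 1:12)
  rownames(m) <- sprintf("c%03d", 1:n)
  in1 <- labels == "L1"
  # f1: clean L1 marker (expressed in all L1, none outside)
  m[in1, 1] <- 10L
  # f2: expressed in only 5% of L1 cells -> fails the 10%-in rule for L1
  m[which(in1)[1:2], 2] <- 10L
  # f3: strong in L1 but expressed in 90% of non-L1 cells -> fails 80%-out
  m[in1, 3] <- 20L
  out1 <- which(!in1)
  m[out1[seq_len(ceiling(0.9 * length(out1)))], 3] <- 1L
  # f4: expressed in exactly half the cells of every label at one level:
  # identical distributions, p = 1 -> fails only the p-value rule
  m[, 4] <- rep(c(0L, 5L), n / 2)
  # f5: clean L2 marker
  m[labels == "L2", 5] <- 8L
  # f6: clean L3 marker
  m[labels == "L3", 6] <- 8L
  # remaining features: flat zeros (never pass the in-fraction rule),
  # except f12 which tops every cell up to the same total so that
  # library-size normalisation is a uniform scaling (keeps f04's
  # distribution identical across labels; f12 itself is expressed
  # everywhere and so fails the 80%-out rule)
  m[, 12] <- 100L - rowSums(m)
  cm <- CellMatrix(m, batch = rep("b", n), label = labels)

  res <- wilcoxonMarkers(cm, nPerLabel = 200)
  expect_true(all(c("f01", "f05", "f06") %in% res$features))
  expect_false("f02" %in% res$features)
  expect_false("f03" %in% res$features)
  expect_false("f04" %in% res$features)

  # independent check that f4 passes both expression-fraction rules and
  # fails only on the p-value rule
  lognorm <- log1p(m / rowSums(m) * 1e4)
  p_f4 <- wilcox.test(lognorm[in1, 4], lognorm[!in1, 4], exact = FALSE)$p.value
  expect_gt(p_f4, 0.1)
  expect_gte(mean(m[in1, 4] > 0), 0.1)
  expect_lte(mean(m[!in1, 4] > 0), 0.8)

  inter <- suppressWarnings(
    wilcoxonMarkers(cm, combine = "intersection")
  )
  expect_length(inter$features, 0)
  expect_warning(
    wilcoxonMarkers(cm, combine = "intersection"),
    "empty set"
  )
})
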