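# Count and embedding generators plus the fixture integrator.

test_that("simulateCounts is a pure function of its config", {
  cfg <- miniSimConfig(seed = 5, nFeatures = 60)
  d1 <- simulateCounts(cfg)
  d2 <- simulateCounts(cfg)
  expect_identical(counts(reference(d1)), counts(reference(d2)))
  expect_identical(counts(query(d1)), counts(query(d2)))
  d3 <- simulateCounts(miniSimConfig(seed = 6, nFeatures = 60))
  expect_false(identical(counts(reference(d1)), counts(reference(d3))))
})

test_that("per-gene mean counts match the analytic negative binomial mean", {
  # one label, no DE, no batch effects, no extra noise, flat library sizes
  cfg <- simConfig(
    nFeatures = 200,
    labelSpec = data.frame(
      name = c("A", "B"), n_cells = c(1000, 10),
      de_prob = 0, de_scale = 0, noise_sd = 0
    ),
    batchSpec = data.frame(
      name = c("b1", "b2"), depth_factor = 1,
      n_cells_factor = 1
    ),
    queryBatches = "b2", unseenLabels = character(),
    trajectorySpec = NULL, batchLoc = 0, batchSd = 0,
    libLoc = log(2000), libSd = 0, bcv = 0.2, seed = 21
  )
  ds <- simulateCounts(cfg)
  ref <- reference(ds)
  idx <- as.character(cellLabel(ref)) == "A"
  m <- counts(ref)[idx, , drop = FALSE]
  gt <- provenance(ds)$ground_truth
  p_g <- gt$base_means / sum(gt$base_means)
  expected <- 2000 * p_g # every cell has library size exactly 2000
  obs_mean <- colMeans(m)
  # NB variance = mu + mu^2 * bcv^2; compare within 3 standard errors
  se <- sqrt((expected + expected^2 * cfg$bcv^2) / sum(idx))
  frac_within <- mean(abs(obs_mean - expected) <= 3 * se + 1e-9)
  expect_gt(frac_within, 0.97)
})

test_that("batch depth factors scale median library sizes proportionally", {
  cfg <- simConfig(
    nFeatures = 150,
    labelSpec = data.frame(
      name = c("A", "B"), n_cells = c(400, 400),
      de_prob = 0, de_scale = 0, noise_sd = 0
    ),
    batchSpec = data.frame(
      name = c("deep", "shallow"),
      depth_factor = c(1, 0.2), n_cells_factor = 1
    ),
    queryBatches = "shallow", unseenLabels = character(),
    trajectorySpec = NULL, batchLoc = 0, batchSd = 0, seed = 22
  )
  ds <- simulateCounts(cfg)
  med_deep <- median(Matrix::rowSums(counts(reference(ds))))
  med_shallow <- median(Matrix::rowSums(counts(query(ds))))
  expect_lt(abs(med_shallow / med_deep - 0.2), 0.02)
})

test_that("counts are overdispersed relative to Poisson at large n", {
  cfg <- miniSimConfig(seed = 8, nFeatures = 100)
  ds <- simulateCounts(cfg)
  m <- as.matrix(counts(reference(ds)))
  idx <- as.character(cellLabel(reference(ds))) == "TypeA"
  mu <- colMeans(m[idx, ])
  v <- apply(m[idx, ], 2, var)
  keep <- mu > 1
  expect_gt(mean(v[keep] >= mu[keep]), 0.9)
})

test_that("unseen labels appear only in query batches and trajectory steps are logged", {
  ds <- simulateCounts(miniSimConfig(seed = 9))
  expect_false("Rare" %in% as.character(cellLabel(reference(ds))))
  expect_true("Rare" %in% as.character(cellLabel(query(ds))))
  gt <- provenance(ds)$ground_truth
  steps <- gt$trajectory_step
  branch_cells <- names(steps)[!is.na(steps)]
  expect_gt(length(branch_cells), 0)
  expect_true(all(steps[branch_cells] > 0 & steps[branch_cells] <= 1))
})

test_that("simulateEmbedding respects placement rules and determinism", {
  cfg <- embConfig(
    d = 5, labels = c("A", "B", "C", "New"),
    batches = c("b1", "b2", "q"), queryBatches = "q",
    unseenLabels = "New", clusterSd = 1, nPerGroup = 25, seed = 3
  )
  e1 <- simulateEmbedding(cfg)
  e2 <- simulateEmbedding(cfg)
  expect_identical(refCoords(e1$embedding), refCoords(e2$embedding))
  seen_centers <- e1$centers[c("A", "B", "C"), ]
  d_new <- sqrt(rowSums(sweep(seen_centers, 2, e1$centers["New", ])^2))
  expect_true(all(d_new >= 6 * cfg$clusterSd))
  expect_false("New" %in% as.character(e1$refLabels))
  expect_true("New" %in% as.character(e1$queryLabels))

  merged <- simulateEmbedding(embConfig(
    d = 5, labels = c("A", "B", "New"),
    batches = c("b1", "q"), queryBatches = "q", unseenLabels = "New",
    unseenPlacement = "merged", seed = 3
  ))
  expect_equal(merged$centers["New", ], merged$centers["A", ])
})

test_that("zero batch shift produces statistically identical batches", {
  cfg <- embConfig(
    d = 4, labels = c("A", "B"), batches = c("b1", "b2"),
    queryBatches = "b2", batchShiftSd = 0, queryShiftSd = 0,
    nPerGroup = 250, seed = 4
  )
  sim <- simulateEmbedding(cfg)
  x <- refCoords(sim$embedding)
  y <- queryCoords(sim$embedding)
  # same label-center mixture in both batches: compare means per dimension
  pooled_sd <- apply(rbind(x, y), 2, sd)
  diff <- abs(colMeans(x) - colMeans(y)) / (pooled_sd * sqrt(2 / nrow(x)))
  expect_lt(max(diff), 4) # ~z-scores under the null
})

test_that("fixture integrator: removal endpoints and query projection", {
  ds <- miniSplitDataset(seed = 13)
  e0 <- fixtureIntegrate(ds, nPcs = 6, removal = 0)
  expect_equal(
    rbind(refCoords(e0), queryCoords(e0)),
    preIntegration(e0)
  )
  # full removal collapses per-batch centroids
  e1 <- fixtureIntegrate(ds, nPcs = 6, removal = 1)
  centroidSpread <- function(emb) {
    coords <- rbind(refCoords(emb), queryCoords(emb))
    b <- c(
      as.character(cellBatch(reference(ds))),
      as.character(cellBatch(query(ds)))
    )
    cm <- do.call(rbind, lapply(split(seq_along(b), b), function(i) {
      colMeans(coords[i, , drop = FALSE])
    }))
    sum(apply(cm, 2, var))
  }
  expect_lt(centroidSpread(e1), 1e-20)
  # a query cell identical to a reference cell lands on the same spot (pre)
  ref <- reference(ds)
  qry <- query(ds)
  qm <- counts(qry)
  qm[1, ] <- counts(ref)[1, ]
  ds2 <- SplitDataset(
    ref,
    CellMatrix(qm, cellBatch(qry), cellLabel(qry)),
    unseenLabels = unseenLabels(ds)
  )
  e2 <- fixtureIntegrate(ds2, nPcs = 6, removal = 0)
  expect_equal(queryCoords(e2)[1, ], refCoords(e2)[1, ], tolerance = 1e-10)
})

test_that("increasing removal monotonically shrinks batch centroid separation", {
  ds <- miniSplitDataset(seed = 14)
  spread <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(r) {
    emb <- fixtureIntegrate(ds, nPcs = 6, removal = r)
    coords <- rbind(refCoords(emb), queryCoords(emb))
    b <- c(
      as.character(cellBatch(reference(ds))),
      as.character(cellBatch(query(ds)))
    )
    cm <- do.call(rbind, lapply(split(seq_along(b), b), function(i) {
      colMeans(coords[i, , drop = FALSE])
    }))
    mean(dist(cm))
  }, numeric(1))
  expect_true(all(diff(spread) <= 1e-9))
})
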