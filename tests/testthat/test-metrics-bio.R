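# Clustering sweep, bNMI, isolated labels, graph connectivity, ldfDiff.

test_that("bNMI endpoints and equivalence to plain NMI for balanced batches", {
  labels <- rep(c("x", "y", "z"), each = 20)
  batch <- rep(c("b1", "b2"), 30)
  expect_equal(bnmi(labels, labels, batch), 1)
  expect_equal(bnmi(rep("c1", 60), labels, batch), 0)
  set.seed(7)
  clusters <- sample(c("c1", "c2", "c3", "c4"), 60, replace = TRUE)
  expect_equal(
    bnmi(clusters, labels, batch),
    plainNMI(clusters, labels),
    tolerance = 1e-12
  )
  # unbalanced batches: overweighted small batch changes the value
  batch_u <- rep(c("b1", "b2"), c(50, 10))
  expect_false(isTRUE(all.equal(
    bnmi(clusters, labels, batch_u),
    plainNMI(clusters, labels)
  )))
})

test_that("cluster sweep recovers separable labels and breaks ties low", {
  g <- gaussianClusters(rbind(c(0, 0), c(20, 0), c(0, 20)),
    n_per = 30,
    sd = 0.5, seed = 8
  )
  cfg <- metricConfig(knnKGraph = 10, seed = 42)
  best <- clusterSweep(g$coords, function(cl) {
    plainNMI(cl, g$label)
  }, cfg)
  expect_equal(best$value, 1, tolerance = 1e-12)
  expect_length(best$sweep, length(cfg$leidenResolutions))
  # constant objective: the lowest resolution must win the tie
  tied <- clusterSweep(g$coords, function(cl) 0.5, cfg)
  expect_equal(tied$resolution, cfg$leidenResolutions[1])
  sc <- bnmiScore(g$coords, g$label, g$batch, cfg)
  expect_equal(sc$value, 1, tolerance = 1e-9)
})

test_that("isolated labels are those in the fewest batches and score sensibly", {
  # L3 present only in batch b1; L1, L2 in all three batches
  set.seed(9)
  centers <- rbind(c(0, 0), c(8, 0), c(30, 30))
  coords <- rbind(
    sweep(matrix(rnorm(120, 0, 0.6), 60, 2), 2, centers[1, ], `+`),
    sweep(matrix(rnorm(120, 0, 0.6), 60, 2), 2, centers[2, ], `+`),
    sweep(matrix(rnorm(40, 0, 0.6), 20, 2), 2, centers[3, ], `+`)
  )
  labels <- rep(c("L1", "L2", "L3"), c(60, 60, 20))
  batch <- c(
    rep(c("b1", "b2", "b3"), 20), rep(c("b1", "b2", "b3"), 20),
    rep("b1", 20)
  )
  cfg <- metricConfig(knnKGraph = 10, seed = 1)
  res <- isolatedLabelScores(coords, labels, batch, cfg)
  expect_match(res$asw$notes, "isolated=L3")
  expect_gt(res$asw$value, 0.9) # tight far-away cluster
  expect_equal(res$f1$value, 1, tolerance = 1e-12)
  # all labels in all batches: warning and all labels treated as isolated
  expect_warning(
    isolatedLabelScores(
      coords[1:120, ], labels[1:120], batch[1:120],
      cfg
    ),
    "all batches"
  )
})

test_that("isolated label F1 matches an exhaustive search on a tiny instance", {
  # interleaved label: best achievable F1 over candidate clusters
  set.seed(10)
  coords <- matrix(rnorm(60, 0, 1), 30, 2)
  labels <- rep(c("A", "B"), 15)
  batch <- c(rep("b1", 15), rep("b2", 14), "b1")
  cfg <- metricConfig(knnKGraph = 5, seed = 2)
  sweep <- clusterSweep(coords, function(cl) 0, cfg)
  # exhaustive: best F1 of any cluster in any swept clustering, per label
  bestF1 <- function(lab) {
    truth <- labels == lab
    best <- 0
    for (s in sweep$sweep) {
      for (cl in levels(s$clusters)) {
        pred <- s$clusters == cl
        tp <- sum(pred & truth)
        if (tp == 0) next
        f1 <- 2 * tp / (2 * tp + sum(pred & !truth) + sum(!pred & truth))
        best <- max(best, f1)
      }
    }
    best
  }
  # both labels occur in both batches, so both count as isolated (with a
  # warning) and the mean over them must match the exhaustive search
  iso <- suppressWarnings(
    isolatedLabelScores(coords, labels, batch, cfg, sweep = sweep)
  )
  presence <- table(labels, batch) > 0
  isolated <- names(which(rowSums(presence) == min(rowSums(presence))))
  expected <- mean(vapply(isolated, bestF1, numeric(1)))
  expect_equal(iso$f1$value, expected, tolerance = 1e-12)
})

test_that("graph connectivity counts largest components per label", {
  # one label split into two far blobs of 6 and 4 cells: k small keeps them
  # disconnected
  set.seed(11)
  blob1 <- matrix(rnorm(12, 0, 0.1), 6, 2)
  blob2 <- sweep(matrix(rnorm(8, 0, 0.1), 4, 2), 2, c(50, 0), `+`)
  other <- sweep(matrix(rnorm(40, 0, 0.1), 20, 2), 2, c(-50, 0), `+`)
  coords <- rbind(blob1, blob2, other)
  labels <- c(rep("split", 10), rep("solid", 20))
  cfg <- metricConfig(knnKGraph = 3)
  sc <- graphConnectivity(coords, labels, cfg)
  expect_equal(sc$value, mean(c(6 / 10, 1)))
})

test_that("label subgraph component sizes agree with a union-find oracle", {
  set.seed(12)
  coords <- matrix(rnorm(80), 40, 2)
  labels <- rep(c("A", "B"), each = 20)
  k <- 4
  nn <- scMapBench:::knnSearch(coords, k)
  unionFind <- function(idx) {
    parent <- seq_along(idx)
    find <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    pos <- match(seq_len(nrow(coords)), idx)
    for (i in seq_along(idx)) {
      for (j in nn$index[idx[i], ]) {
        if (!is.na(pos[j])) {
          ri <- find(i)
          rj <- find(pos[j])
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
    # also the reverse direction (undirected graph)
    for (i in seq_along(idx)) {
      for (j in seq_along(idx)) {
        if (idx[i] %in% nn$index[idx[j], ]) {
          ri <- find(i)
          rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
    roots <- vapply(seq_along(idx), find, integer(1))
    max(table(roots)) / length(idx)
  }
  oracle <- mean(c(unionFind(which(labels == "A")), unionFind(which(labels == "B"))))
  sc <- graphConnectivity(coords, labels, metricConfig(knnKGraph = k))
  expect_equal(sc$value, oracle, tolerance = 1e-12)
})

test_that("ldfDiff is exact on identity and decreases when structure collapses", {
  set.seed(13)
  # dense core + sparse halo in one batch
  core <- matrix(rnorm(100, 0, 0.2), 50, 2)
  halo <- matrix(rnorm(100, 0, 3), 50, 2)
  pre <- rbind(core, halo)
  emb_id <- JointEmbedding(pre[1:80, ], pre[81:100, ], preIntegration = pre)
  batch <- rep("b1", 100)
  cfg <- metricConfig(knnKGraph = 10, ldfBound = 1)
  expect_equal(ldfDiff(emb_id, batch, cfg)$value, 1)
  # integration that spreads the dense cluster uniformly
  post <- matrix(runif(200, -3, 3), 100, 2)
  emb_bad <- JointEmbedding(post[1:80, ], post[81:100, ], preIntegration = pre)
  expect_lt(ldfDiff(emb_bad, batch, cfg)$value, 1)
})
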