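# Mahalanobis cell/label distances and kNN correlation.

test_that("cell distance self-map sits at the boundary quantile", {
  set.seed(20)
  n <- 1000
  d <- 10
  labels <- rep(paste0("L", 1:5), each = n / 5)
  centers <- matrix(rnorm(5 * d, 0, 6), 5, d)
  coords <- centers[rep(1:5, each = n / 5), ] + matrix(rnorm(n * d), n, d)
  emb <- JointEmbedding(coords, coords)
  sc <- cellDistance(emb, labels, labels, character(), metricConfig())
  expect_equal(sc$value, 0.90, tolerance = 2 / n + 1e-9)
})

test_that("displaced queries fall outside every boundary", {
  set.seed(21)
  g <- gaussianClusters(rbind(c(0, 0), c(10, 0)), n_per = 100, sd = 1)
  emb <- JointEmbedding(g$coords, g$coords + 100)
  sc <- cellDistance(
    emb, g$label, g$label, character(),
    metricConfig()
  )
  expect_equal(sc$value, 0)
})

test_that("Mahalanobis distance reduces to Euclidean for identity covariance", {
  set.seed(22)
  # large sample from an isotropic 2-D Gaussian: covariance ~ I
  x <- matrix(rnorm(40000), 20000, 2)
  fit <- scMapBench:::shrunkCovariance(x, eps = 0)
  pts <- rbind(c(3, 4), c(0, 0), c(-1, 1))
  d <- scMapBench:::mahalanobisDist(pts, fit)
  euclid <- sqrt(rowSums(sweep(pts, 2, fit$mean)^2))
  expect_equal(d, euclid, tolerance = 0.05)
  # and exactly against stats::mahalanobis with the same fitted covariance
  expect_equal(
    d^2,
    stats::mahalanobis(pts, fit$mean, fit$sigma),
    tolerance = 1e-9
  )
})

test_that("label distance scores centroid displacement against spread", {
  set.seed(23)
  g <- gaussianClusters(rbind(c(0, 0), c(20, 0)), n_per = 100, sd = 1)
  emb_same <- JointEmbedding(g$coords, g$coords)
  sc <- labelDistance(emb_same, g$label, g$label, character(), metricConfig())
  expect_gt(sc$value, 0.95) # coincident centroids
  # one label displaced beyond its query spread (score 0), other coincident
  shifted <- g$coords
  shifted[g$label == "L2", 1] <- shifted[g$label == "L2", 1] + 100
  emb_mix <- JointEmbedding(g$coords, shifted)
  sc2 <- labelDistance(emb_mix, g$label, g$label, character(), metricConfig())
  expect_lt(abs(sc2$value - mean(c(sc$value, 0))), 0.05)
  # labels under the query-cell minimum are skipped
  small_q <- c(rep("L1", 181), rep("L2", 19))
  sc3 <- labelDistance(
    emb_same, g$label, small_q, character(),
    metricConfig()
  )
  expect_match(sc3$notes, "labels=1")
})

test_that("kNN correlation is 1 under isometry and matches a brute-force oracle", {
  ds <- miniSplitDataset(seed = 24, nFeatures = 60)
  qry <- query(ds)
  # joint embedding = rotation + translation of the per-batch PCA structure:
  # build it per batch from the same normalised data the metric uses
  x <- scMapBench:::denseCounts(scMapBench:::logNormalize(counts(qry)))
  nPcs <- 5
  joint <- matrix(0, nCells(qry), nPcs)
  theta <- 0.7
  rot <- diag(nPcs)
  rot[1:2, 1:2] <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  for (b in levels(droplevels(cellBatch(qry)))) {
    idx <- which(as.character(cellBatch(qry)) == b)
    pca <- prcomp(x[idx, ], rank. = nPcs, center = TRUE, scale. = FALSE)
    joint[idx, ] <- pca$x %*% rot + 5
  }
  emb <- JointEmbedding(
    matrix(0, nCells(reference(ds)), nPcs), joint
  )
  cfg <- metricConfig(knnCorrK = 20)
  sc <- knnCorrelation(ds, emb, nPcs = nPcs, cfg = cfg)
  expect_equal(sc$value, 1, tolerance = 1e-9)

  # brute-force Spearman oracle on a scrambled embedding
  set.seed(25)
  joint_bad <- matrix(rnorm(length(joint)), nrow(joint), nPcs)
  emb_bad <- JointEmbedding(matrix(0, nCells(reference(ds)), nPcs), joint_bad)
  sc_bad <- knnCorrelation(ds, emb_bad, nPcs = nPcs, cfg = cfg)
  spearman <- function(a, b) {
    ra <- rank(a)
    rb <- rank(b)
    sum((ra - mean(ra)) * (rb - mean(rb))) /
      sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  }
  batch_means <- vapply(levels(droplevels(cellBatch(qry))), function(b) {
    idx <- which(as.character(cellBatch(qry)) == b)
    pca <- prcomp(x[idx, ], rank. = nPcs, center = TRUE, scale. = FALSE)
    k <- min(cfg$knnCorrK, length(idx) - 2L)
    D <- as.matrix(dist(pca$x))
    Dj <- as.matrix(dist(joint_bad[idx, ]))
    cell_scores <- vapply(seq_along(idx), function(i) {
      ord <- order(D[i, -i])
      nbr <- setdiff(seq_along(idx), i)[ord][seq_len(k)]
      if (sd(D[i, nbr]) == 0 || sd(Dj[i, nbr]) == 0) {
        return(0)
      }
      (spearman(D[i, nbr], Dj[i, nbr]) + 1) / 2
    }, numeric(1))
    mean(cell_scores)
  }, numeric(1))
  expect_equal(sc_bad$value, mean(batch_means), tolerance = 1e-9)
})

test_that("degenerate neighbour distances score zero for the cell", {
  # a query batch whose joint coordinates are all identical: every
  # neighbour distance ties, the correlation is undefined, score 0
  ds <- miniSplitDataset(seed = 26, nFeatures = 50)
  nPcs <- 4
  joint <- matrix(1, nCells(query(ds)), nPcs)
  emb <- JointEmbedding(matrix(0, nCells(reference(ds)), nPcs), joint)
  sc <- knnCorrelation(ds, emb, nPcs = nPcs, cfg = metricConfig(knnCorrK = 15))
  expect_equal(sc$value, 0)
})
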