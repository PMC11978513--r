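# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; nothing is read from disk.

toyCellMatrix <- function(counts, batch, label) {
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("c%03d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("g%03d", seq_len(ncol(counts)))
  }
  CellMatrix(counts, batch = batch, label = label)
}

randomCellMatrix <- function(n_cells = 60, n_features = 40, seed = 1,
                             n_batches = 2, n_labels = 3, lambda = 5) {
  set.seed(seed)
  m <- matrix(rpois(n_cells * n_features, lambda), n_cells, n_features)
  toyCellMatrix(
    m,
    batch = rep_len(paste0("b", seq_len(n_batches)), n_cells),
    label = rep_len(paste0("L", seq_len(n_labels)), n_cells)
  )
}

# Gaussian cluster embedding with explicit centers; returns coords + factors.
gaussianClusters <- function(centers, n_per = 30, sd = 0.5, seed = 1,
                             batch_cycle = 2) {
  set.seed(seed)
  k <- nrow(centers)
  coords <- do.call(rbind, lapply(seq_len(k), function(i) {
    sweep(
      matrix(rnorm(n_per * ncol(centers), 0, sd), n_per, ncol(centers)),
      2, centers[i, ], `+`
    )
  }))
  rownames(coords) <- sprintf("cell%04d", seq_len(nrow(coords)))
  list(
    coords = coords,
    label = factor(rep(paste0("L", seq_len(k)), each = n_per)),
    batch = factor(rep_len(paste0("b", seq_len(batch_cycle)), nrow(coords)))
  )
}

# Small prepared SplitDataset for pipeline-level tests.
miniSimConfig <- function(seed = 1, nFeatures = 120) {
  simConfig(
    nFeatures = nFeatures,
    labelSpec = data.frame(
      name = c("Progenitor", "Terminal1", "Terminal2", "TypeA", "Rare"),
      n_cells = c(25, 25, 25, 30, 12),
      de_prob = c(0.2, 0.2, 0.2, 0.3, 0.4),
      de_scale = c(0.5, 0.5, 0.5, 0.6, 0.9)
    ),
    batchSpec = data.frame(
      name = c("B1", "B2", "Q1", "Q2"),
      depth_factor = c(1, 1, 0.5, 0.5),
      n_cells_factor = c(1, 1, 1, 1)
    ),
    queryBatches = c("Q1", "Q2"),
    unseenLabels = "Rare",
    trajectorySpec = list(
      progenitor = "Progenitor",
      branches = list("Terminal1", "Terminal2"), n_steps = 5
    ),
    seed = seed
  )
}

miniSplitDataset <- function(seed = 1, nFeatures = 120) {
  sim <- simulateCounts(miniSimConfig(seed, nFeatures))
  prepareSplit(combineHalves(sim),
    queryBatches = c("Q1", "Q2"),
    unseenLabels = "Rare", minCounts = 50, minFeatures = 20,
    minLabelCells = 10
  )
}
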