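# Integration (Bio) metrics: Leiden resolution sweep, batch-balanced NMI,
# isolated label scores, graph connectivity and local density factor
# differences.

knnGraph <- function(coords, k) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  k <- min(k, n - 1L)
  nn <- knnSearch(coords, k)
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nn$index)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}

#' Sweep Leiden clustering resolutions and keep the best clustering
#'
#' Builds a kNN graph on the coordinates, runs Leiden (modularity objective)
#' at every resolution in \code{cfg$leidenResolutions} and returns the
#' clustering that maximises the supplied objective. Ties keep the lowest
#' resolution.
#'
#' @param coords coordinate matrix.
#' @param objective function(membership factor) -> numeric score to maximise.
#' @param cfg a [metricConfig()].
#' @return list with \code{clusters} (factor), \code{resolution},
#'   \code{value}, and \code{sweep} (per-resolution clusterings and values).
#' @export
clusterSweep <- function(coords, objective, cfg = metricConfig()) {
  g <- knnGraph(coords, cfg$knnKGraph)
  best <- NULL
  sweep_out <- list()
  for (res in cfg$leidenResolutions) {
    cl <- withSeed(cfg$seed + round(res * 1000), {
      igraph::cluster_leiden(g,
        objective_function = "modularity",
        resolution = res, n_iterations = 3
      )
    })
    membership <- factor(igraph::membership(cl))
    val <- objective(membership)
    sweep_out[[length(sweep_out) + 1L]] <- list(
      resolution = res, clusters = membership, value = val
    )
    if (is.null(best) || val > best$value + 1e-12) {
      best <- list(clusters = membership, resolution = res, value = val)
    }
  }
  best$sweep <- sweep_out
  best
}

# Batch-balanced mutual information: every batch contributes equal total
# weight to the cluster x label contingency table.
weightedNMI <- function(clusters, labels, weights) {
  clusters <- factor(clusters)
  labels <- factor(labels)
  if (nlevels(droplevels(clusters)) < 2 || nlevels(droplevels(labels)) < 2) {
    return(0)
  }
  w <- weights / sum(weights)
  joint <- tapply(w, list(clusters, labels), sum, default = 0)
  pr <- rowSums(joint)
  pc <- colSums(joint)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / (pr[row(joint)[nz]] * pc[col(joint)[nz]])))
  hr <- -sum(ifelse(pr > 0, pr * log(pr), 0))
  hc <- -sum(ifelse(pc > 0, pc * log(pc), 0))
  if (hr + hc == 0) {
    return(0)
  }
  mi / ((hr + hc) / 2)
}

#' Batch-balanced normalized mutual information of a clustering
#'
#' NMI (arithmetic-mean normalisation) between clusters and labels computed
#' on a contingency table where each cell carries weight
#' 1 / (B * n_batch(cell)), so every batch contributes equal total weight.
#' With equal-size batches this reduces to plain NMI.
#'
#' @param clusters cluster membership factor.
#' @param labels ground-truth labels.
#' @param batch batch factor used for balancing.
#' @return numeric bNMI in \[0, 1\].
#' @export
bnmi <- function(clusters, labels, batch) {
  batch <- factor(batch)
  nb <- table(batch)
  w <- 1 / (nlevels(batch) * as.numeric(nb[batch]))
  weightedNMI(clusters, labels, w)
}

#' bNMI metric with resolution sweep
#'
#' Runs [clusterSweep()] with bNMI as the objective and reports the best
#' value as the metric score.
#'
#' @inheritParams clusterSweep
#' @param labels reference labels.
#' @param batch reference batches.
#' @param sweep optional precomputed [clusterSweep()] result to reuse.
#' @return a `MetricScore` in the bio category.
#' @export
bnmiScore <- function(coords, labels, batch, cfg = metricConfig(),
                      sweep = NULL) {
  if (is.null(sweep)) {
    sweep <- clusterSweep(coords, function(cl) bnmi(cl, labels, batch), cfg)
  }
  vals <- vapply(sweep$sweep, function(s) bnmi(s$clusters, labels, batch),
    numeric(1)
  )
  best <- which.max(vals > max(vals) - 1e-12) # lowest resolution at the max
  metricScore("bnmi", "bio", min(max(vals[best], 0), 1), nrow(coords),
    notes = paste0("resolution=", sweep$sweep[[best]]$resolution)
  )
}

binaryF1 <- function(pred, truth) {
  tp <- sum(pred & truth)
  if (tp == 0) {
    return(0)
  }
  prec <- tp / sum(pred)
  rec <- tp / sum(truth)
  2 * prec * rec / (prec + rec)
}

#' Isolated label scores (silhouette and cluster F1 variants)
#'
#' Isolated labels are those present in the minimum number of batches. The
#' silhouette variant scores, for each isolated label, the mean rescaled
#' silhouette width (s + 1) / 2 of the label's cells against all other cells.
#' The F1 variant sweeps Leiden clusterings over resolutions and takes, per
#' isolated label, the maximum F1 between any cluster and the label. Both
#' report the mean over isolated labels.
#'
#' @param coords reference coordinates.
#' @param labels reference labels.
#' @param batch reference batches.
#' @param cfg a [metricConfig()].
#' @param sweep optional precomputed [clusterSweep()] result to reuse.
#' @return list of two `MetricScore`s: \code{asw} and \code{f1}.
#' @export
isolatedLabelScores <- function(coords, labels, batch, cfg = metricConfig(),
                                sweep = NULL) {
  labels <- droplevels(factor(labels))
  batch <- droplevels(factor(batch))
  presence <- table(labels, batch) > 0
  n_batches <- rowSums(presence)
  min_b <- min(n_batches)
  isolated <- names(n_batches)[n_batches == min_b]
  if (min_b == nlevels(batch)) {
    warning("every label is present in all batches; ",
      "isolated label scores computed over all labels")
  }
  d <- stats::dist(coords)
  asw_per_label <- vapply(isolated, function(l) {
    grp <- as.integer(labels == l) + 1L
    sil <- cluster::silhouette(grp, d)
    mean((sil[grp == 2L, "sil_width"] + 1) / 2)
  }, numeric(1))
  # maximum cluster F1 over the whole resolution sweep
  if (is.null(sweep)) sweep <- clusterSweep(coords, function(cl) 0, cfg)
  f1_per_label <- vapply(isolated, function(l) {
    truth <- labels == l
    best <- 0
    for (s in sweep$sweep) {
      for (cl_id in levels(s$clusters)) {
        best <- max(best, binaryF1(s$clusters == cl_id, truth))
      }
    }
    best
  }, numeric(1))
  list(
    asw = metricScore("isolated_label_asw", "bio", mean(asw_per_label),
      nrow(coords),
      notes = paste0("isolated=", paste(isolated, collapse = ","))
    ),
    f1 = metricScore("isolated_label_f1", "bio", mean(f1_per_label),
      nrow(coords))
  )
}

#' Graph connectivity of labels in the kNN graph
#'
#' For each label, the fraction of its cells contained in the largest
#' connected component of the label-restricted kNN subgraph; the score is the
#' mean over labels. Size-1 labels contribute 1.
#'
#' @param coords reference coordinates.
#' @param labels reference labels.
#' @param cfg a [metricConfig()].
#' @return a `MetricScore` in the bio category.
#' @export
graphConnectivity <- function(coords, labels, cfg = metricConfig()) {
  labels <- droplevels(factor(labels))
  g <- knnGraph(coords, cfg$knnKGraph)
  per_label <- vapply(levels(labels), function(l) {
    idx <- which(labels == l)
    if (length(idx) <= 1) {
      return(1)
    }
    sub <- igraph::induced_subgraph(g, idx)
    comp <- igraph::components(sub)
    max(comp$csize) / length(idx)
  }, numeric(1))
  metricScore("graph_connectivity", "bio", mean(per_label), nrow(coords))
}

# Local density from kNN distances (reciprocal mean neighbour distance) and
# the local density factor: a cell's density relative to the mean density of
# its k neighbours.
localDensityFactor <- function(coords, k) {
  coords <- as.matrix(coords)
  k <- min(k, nrow(coords) - 1L)
  nn <- knnSearch(coords, k)
  dens <- 1 / (rowMeans(nn$dist) + 1e-12)
  neigh_dens <- rowMeans(matrix(dens[nn$index], nrow(coords), k))
  dens / (neigh_dens + 1e-12)
}

#' Local density factor difference between pre- and post-integration spaces
#'
#' Each cell's local density factor (its kNN-kernel density divided by the
#' mean density of its neighbours) is computed within the cell's own batch in
#' the pre-integration embedding and within the full integrated embedding.
#' The cell score is min(|log2 LDF_post - log2 LDF_pre|, u) / u with bound
#' \code{u = cfg$ldfBound}; the metric is 1 minus the mean cell score, so 1
#' means local density structure is perfectly preserved.
#'
#' @param emb a [JointEmbedding-class]; the pre-integration embedding is
#'   required.
#' @param batch batch factor over reference then query cells.
#' @param cfg a [metricConfig()].
#' @return a `MetricScore` in the bio category.
#' @export
ldfDiff <- function(emb, batch, cfg = metricConfig()) {
  pre <- preIntegration(emb)
  assertThat(!is.null(pre), "ldfDiff requires a pre-integration embedding")
  post <- rbind(refCoords(emb), queryCoords(emb))
  batch <- factor(batch)
  assertThat(length(batch) == nrow(post), "batch must cover all cells")
  k <- cfg$knnKGraph
  ldf_post <- localDensityFactor(post, k)
  ldf_pre <- numeric(nrow(pre))
  for (b in levels(batch)) {
    idx <- which(batch == b)
    kb <- min(k, length(idx) - 1L)
    if (kb < 1) {
      ldf_pre[idx] <- 1
      next
    }
    ldf_pre[idx] <- localDensityFactor(pre[idx, , drop = FALSE], kb)
  }
  diffs <- abs(log2(ldf_post + 1e-12) - log2(ldf_pre + 1e-12))
  cell_score <- pmin(diffs, cfg$ldfBound) / cfg$ldfBound
  metricScore("ldf_diff", "bio", 1 - mean(cell_score), nrow(post))
}
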