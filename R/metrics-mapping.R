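# Mapping quality metrics: Mahalanobis cell/label distances and kNN
# correlation between query-batch PCA space and the joint embedding.

# Per-reference-label Mahalanobis machinery: shrunk covariance fit plus the
# boundary at the configured quantile of reference self-distances.
referenceLabelFits <- function(ref_coords, ref_labels, cfg) {
  ref_labels <- droplevels(factor(ref_labels))
  fits <- list()
  for (l in levels(ref_labels)) {
    idx <- which(ref_labels == l)
    fit <- shrunkCovariance(ref_coords[idx, , drop = FALSE],
      eps = cfg$covShrinkageEps
    )
    self_d <- mahalanobisDist(ref_coords[idx, , drop = FALSE], fit)
    fit$boundary <- as.numeric(quantile(self_d, cfg$cellDistQuantile, type = 7))
    fit$n <- length(idx)
    fits[[l]] <- fit
  }
  fits
}

#' Cell distance mapping score
#'
#' For every reference label, fits the label's distribution (mean and shrunk
#' covariance) in the integrated space and takes the
#' \code{cellDistQuantile} (default 90th) quantile of the reference cells'
#' own Mahalanobis distances as a boundary. The score is 1 minus the
#' proportion of mapped query cells (of labels shared with the reference;
#' unseen labels excluded) falling strictly outside their label's boundary.
#'
#' @param emb a [JointEmbedding-class].
#' @param refLabels,queryLabels ground-truth labels for the two halves.
#' @param unseenLabels labels excluded from scoring.
#' @param cfg a [metricConfig()].
#' @return a `MetricScore` in the mapping category.
#' @export
cellDistance <- function(emb, refLabels, queryLabels,
                         unseenLabels = character(), cfg = metricConfig()) {
  fits <- referenceLabelFits(refCoords(emb), refLabels, cfg)
  q_labels <- as.character(queryLabels)
  eligible <- !(q_labels %in% unseenLabels)
  unmatched <- setdiff(unique(q_labels[eligible]), names(fits))
  if (length(unmatched)) {
    warning(
      "query label(s) absent from reference and not declared unseen: ",
      paste(unmatched, collapse = ", ")
    )
    eligible <- eligible & !(q_labels %in% unmatched)
  }
  assertThat(any(eligible), "no query cells with labels shared with the reference")
  qc <- queryCoords(emb)
  outside <- logical(sum(eligible))
  pos <- 0L
  for (l in unique(q_labels[eligible])) {
    idx <- which(eligible & q_labels == l)
    d <- mahalanobisDist(qc[idx, , drop = FALSE], fits[[l]])
    outside[pos + seq_along(idx)] <- d > fits[[l]]$boundary
    pos <- pos + length(idx)
  }
  metricScore("cell_distance", "mapping", 1 - mean(outside), sum(eligible))
}

#' Label distance mapping score
#'
#' For each label shared between reference and query with at least
#' \code{labelMinQueryCells} query cells, computes the Mahalanobis distance D
#' (reference label covariance) between the query centroid and the reference
#' centroid, bounds it by the maximum distance M of the label's query cells
#' to their own centroid, and scores the label 1 - min(D / M, 1). The metric
#' is the mean over eligible labels.
#'
#' @inheritParams cellDistance
#' @return a `MetricScore` in the mapping category.
#' @export
labelDistance <- function(emb, refLabels, queryLabels,
                          unseenLabels = character(), cfg = metricConfig()) {
  fits <- referenceLabelFits(refCoords(emb), refLabels, cfg)
  q_labels <- as.character(queryLabels)
  qc <- queryCoords(emb)
  shared <- intersect(setdiff(unique(q_labels), unseenLabels), names(fits))
  shared <- shared[vapply(shared, function(l) {
    sum(q_labels == l) >= cfg$labelMinQueryCells
  }, logical(1))]
  assertThat(length(shared) >= 1, "no eligible shared labels")
  scores <- vapply(shared, function(l) {
    idx <- which(q_labels == l)
    centroid <- colMeans(qc[idx, , drop = FALSE])
    fit <- fits[[l]]
    D <- mahalanobisDist(matrix(centroid, 1), fit)
    centered_fit <- fit
    centered_fit$mean <- centroid
    M <- max(mahalanobisDist(qc[idx, , drop = FALSE], centered_fit))
    if (M <= 0) {
      return(if (D <= 0) 1 else 0)
    }
    1 - min(D / M, 1)
  }, numeric(1))
  metricScore("label_distance", "mapping", mean(scores),
    sum(q_labels %in% shared),
    notes = paste0("labels=", length(shared))
  )
}

#' kNN correlation between query-batch PCA and the joint embedding
#'
#' For each query batch, recomputes a PCA from that batch's counts alone (on
#' the supplied features), finds each cell's \code{knnCorrK} nearest
#' neighbours in that space, and computes the Spearman correlation between
#' the distances to those neighbours and the distances to the same cells in
#' the joint embedding. Per-cell scores are (rho + 1) / 2 (0 when the
#' correlation is undefined); the metric is the mean over cells within each
#' batch, then the mean across batches. Excluded from category means by
#' default.
#'
#' @param ds a [SplitDataset-class] (query counts are used).
#' @param emb a [JointEmbedding-class].
#' @param features optional feature subset used for the per-batch PCA.
#' @param nPcs dimensions of the per-batch PCA (default 10).
#' @param cfg a [metricConfig()].
#' @return a `MetricScore` in the mapping category.
#' @export
knnCorrelation <- function(ds, emb, features = NULL, nPcs = 10,
                           cfg = metricConfig()) {
  qry <- query(ds)
  if (!is.null(features)) qry <- qry[, features]
  batches <- levels(droplevels(cellBatch(qry)))
  joint <- queryCoords(emb)
  batch_means <- vapply(batches, function(b) {
    idx <- which(as.character(cellBatch(qry)) == b)
    x <- denseCounts(logNormalize(counts(qry)[idx, , drop = FALSE]))
    npc <- min(nPcs, length(idx) - 1L, ncol(x))
    pca <- prcomp(x, rank. = npc, center = TRUE, scale. = FALSE)
    k <- cfg$knnCorrK
    if (length(idx) <= k + 1) {
      k <- max(2L, length(idx) - 2L)
      warning("knnCorrK reduced to ", k, " for batch ", b)
    }
    nn <- knnSearch(pca$x, k)
    cell_scores <- vapply(seq_along(idx), function(i) {
      d_pca <- nn$dist[i, ]
      target <- joint[idx[nn$index[i, ]], , drop = FALSE]
      d_joint <- sqrt(rowSums(sweep(target, 2, joint[idx[i], ])^2))
      if (sd(d_pca) == 0 || sd(d_joint) == 0) {
        return(0)
      }
      (cor(d_pca, d_joint, method = "spearman") + 1) / 2
    }, numeric(1))
    mean(cell_scores)
  }, numeric(1))
  metricScore("knn_correlation", "mapping", mean(batch_means),
    nCells(qry),
    notes = "optional; excluded from category means"
  )
}
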