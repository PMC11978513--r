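# Unseen population metrics: classifier uncertainty, Mahalanobis separation
# of unseen cells and labels from the reference, and a Milo-style
# neighbourhood differential abundance score.

#' Classifier uncertainty on unseen populations
#'
#' 1 minus the mean assigned-class probability over query cells from unseen
#' populations: a confident classifier on cells that have no correct class
#' scores 0. Excluded from category means by default.
#'
#' @param tr a [TransferResult-class].
#' @param unseenMask logical per query cell: TRUE for unseen-population cells.
#' @return a `MetricScore` in the unseen category.
#' @export
unseenUncertainty <- function(tr, unseenMask) {
  assertThat(any(unseenMask), "no unseen cells")
  prob <- classProbabilities(tr)[unseenMask, , drop = FALSE]
  value <- 1 - mean(apply(prob, 1, max))
  metricScore("unseen_uncertainty", "unseen", value, sum(unseenMask),
    notes = "optional; excluded from category means"
  )
}

#' Unseen cell distance score
#'
#' For each unseen query cell, finds its nearest reference label by
#' Mahalanobis distance and checks whether that distance exceeds the label's
#' reference boundary (the \code{cellDistQuantile} quantile of reference
#' self-distances). The score is the proportion of unseen cells outside their
#' nearest label's boundary: well-separated unseen populations score 1.
#'
#' @inheritParams cellDistance
#' @return a `MetricScore` in the unseen category.
#' @export
unseenCellDistance <- function(emb, refLabels, queryLabels, unseenLabels,
                               cfg = metricConfig()) {
  q_labels <- as.character(queryLabels)
  unseen_idx <- which(q_labels %in% unseenLabels)
  assertThat(length(unseen_idx) > 0, "no unseen cells")
  fits <- referenceLabelFits(refCoords(emb), refLabels, cfg)
  qc <- queryCoords(emb)[unseen_idx, , drop = FALSE]
  dist_mat <- vapply(fits, function(f) mahalanobisDist(qc, f),
    numeric(nrow(qc))
  )
  dist_mat <- matrix(dist_mat, nrow = nrow(qc))
  nearest <- max.col(-dist_mat, ties.method = "first")
  boundaries <- vapply(fits, `[[`, numeric(1), "boundary")
  outside <- dist_mat[cbind(seq_len(nrow(qc)), nearest)] > boundaries[nearest]
  metricScore("unseen_cell_distance", "unseen", mean(outside),
    length(unseen_idx))
}

#' Unseen label distance score
#'
#' For each unseen label with at least \code{labelMinQueryCells} query cells:
#' D is the Mahalanobis distance from the unseen label's query centroid to
#' the nearest reference label centroid (under that label's covariance) and M
#' the maximum distance of the unseen label's cells to their own centroid
#' under the same covariance. The label scores min(D / M, 1) and the metric
#' is the mean over unseen labels; if every unseen label is too small the
#' score is 0 with a note.
#'
#' @inheritParams cellDistance
#' @return a `MetricScore` in the unseen category.
#' @export
unseenLabelDistance <- function(emb, refLabels, queryLabels, unseenLabels,
                                cfg = metricConfig()) {
  q_labels <- as.character(queryLabels)
  fits <- referenceLabelFits(refCoords(emb), refLabels, cfg)
  qc <- queryCoords(emb)
  usable <- unseenLabels[vapply(unseenLabels, function(l) {
    sum(q_labels == l) >= cfg$labelMinQueryCells
  }, logical(1))]
  if (!length(usable)) {
    return(metricScore("unseen_label_distance", "unseen", 0, 0L,
      notes = "all unseen labels below the query cell minimum"
    ))
  }
  scores <- vapply(usable, function(l) {
    idx <- which(q_labels == l)
    centroid <- colMeans(qc[idx, , drop = FALSE])
    d_to_refs <- vapply(fits, function(f) {
      mahalanobisDist(matrix(centroid, 1), f)
    }, numeric(1))
    nearest <- which.min(d_to_refs)
    fit <- fits[[nearest]]
    D <- d_to_refs[nearest]
    centered <- fit
    centered$mean <- centroid
    M <- max(mahalanobisDist(qc[idx, , drop = FALSE], centered))
    if (M <= 0) {
      return(if (D > 0) 1 else 0)
    }
    min(D / M, 1)
  }, numeric(1))
  metricScore("unseen_label_distance", "unseen", mean(scores),
    sum(q_labels %in% usable),
    notes = paste0("labels=", length(usable))
  )
}

#' Milo-style unseen population detection score
#'
#' Samples index cells (deterministically from cell-id hashes so the result
#' is independent of row order), takes each index cell's k nearest
#' neighbours in the joint embedding as a neighbourhood
#' (k = \code{miloKPerBatch} x n_batches capped at \code{miloKMax}), and
#' tests each neighbourhood for association with query status: a negative
#' binomial regression of batch-level neighbourhood counts on the batch's
#' query indicator with a log batch-size offset, falling back to an exact
#' one-sided binomial test of query membership against the overall query
#' fraction when the regression fails. P-values are Benjamini-Hochberg
#' adjusted across neighbourhoods; each neighbourhood is assigned to the
#' majority label among its members (ties: the index cell's label). Each
#' unseen label scores the proportion of its neighbourhoods with adjusted
#' p below \code{miloFdr}; the metric is the mean over unseen labels, with
#' labels owning no neighbourhood scoring 0.
#'
#' @param emb a [JointEmbedding-class].
#' @param batch batch factor over reference then query cells.
#' @param isQuery logical per cell (reference then query order).
#' @param labels per-cell labels (reference then query order).
#' @param unseenLabels unseen population labels.
#' @param cfg a [metricConfig()].
#' @param cellIds optional cell identifiers used for order-independent
#'   subsampling (defaults to embedding rownames or positional ids).
#' @return a `MetricScore` in the unseen category.
#' @export
miloScore <- function(emb, batch, isQuery, labels, unseenLabels,
                      cfg = metricConfig(), cellIds = NULL) {
  coords <- rbind(refCoords(emb), queryCoords(emb))
  n <- nrow(coords)
  batch <- factor(batch)
  labels <- as.character(labels)
  assertThat(nlevels(droplevels(batch)) >= 2, "need >= 2 batches")
  assertThat(length(isQuery) == n && length(labels) == n && length(batch) == n,
    "annotation lengths must match the embedding"
  )
  if (is.null(cellIds)) {
    cellIds <- rownames(coords)
    if (is.null(cellIds)) cellIds <- as.character(seq_len(n))
  }
  n_index <- min(n, max(cfg$miloSubsetMin, ceiling(cfg$miloSubsetFrac * n)))
  hash <- stableHash(cellIds, cfg$seed)
  index_cells <- order(hash)[seq_len(n_index)]
  k <- min(cfg$miloKPerBatch * nlevels(droplevels(batch)), cfg$miloKMax)
  k <- min(k, n - 1L)
  nn <- knnSearch(coords, k, query = coords[index_cells, , drop = FALSE])
  batch_sizes <- table(batch)
  batch_is_query <- tapply(isQuery, batch, any)
  q_frac <- mean(isQuery)
  pvals <- numeric(length(index_cells))
  nbhd_label <- character(length(index_cells))
  for (i in seq_along(index_cells)) {
    members <- nn$index[i, ]
    counts_b <- table(factor(batch[members], levels = levels(batch)))
    df <- data.frame(
      count = as.numeric(counts_b),
      is_query = as.numeric(batch_is_query[levels(batch)]),
      offset = log(as.numeric(batch_sizes))
    )
    one_side_empty <- all(counts_b[batch_is_query[levels(batch)]] == 0) ||
      all(counts_b[!batch_is_query[levels(batch)]] == 0)
    p <- if (one_side_empty) {
      # complete separation: the regression cannot estimate the effect
      binom.test(sum(isQuery[members]), length(members),
        p = q_frac, alternative = "greater"
      )$p.value
    } else {
      tryCatch(
      {
        fit <- withCallingHandlers(
          MASS::glm.nb(count ~ is_query + offset(offset), data = df),
          warning = function(w) invokeRestart("muffleWarning")
        )
        if (!fit$converged) stop("no convergence")
        co <- summary(fit)$coefficients
        if (!"is_query" %in% rownames(co)) stop("no query term")
        est <- co["is_query", "Estimate"]
        se <- co["is_query", "Std. Error"]
        # complete separation (e.g. a pure-query neighbourhood) inflates the
        # Wald standard error without bound; that is a failed regression
        if (!is.finite(est) || !is.finite(se) || se > 100 || abs(est) > 20) {
          stop("degenerate Wald statistic")
        }
        # one-sided: enrichment in query batches
        pnorm(est / se, lower.tail = FALSE)
      },
      error = function(e) {
        binom.test(sum(isQuery[members]), length(members),
          p = q_frac, alternative = "greater"
        )$p.value
      }
      )
    }
    pvals[i] <- p
    tab <- table(labels[members])
    top <- names(tab)[tab == max(tab)]
    nbhd_label[i] <- if (length(top) == 1) {
      top
    } else if (labels[index_cells[i]] %in% top) {
      labels[index_cells[i]]
    } else {
      top[1]
    }
  }
  padj <- p.adjust(pvals, method = "BH")
  per_label <- vapply(unseenLabels, function(l) {
    idx <- which(nbhd_label == l)
    if (!length(idx)) {
      return(0)
    }
    mean(padj[idx] < cfg$miloFdr)
  }, numeric(1))
  metricScore("milo", "unseen", mean(per_label), n_index,
    notes = paste0("k=", k)
  )
}
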