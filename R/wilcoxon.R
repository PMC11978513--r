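# Vectorised two-sided Wilcoxon rank-sum test (normal approximation with tie
# and continuity correction, replicating stats::wilcox.test(exact = FALSE,
# correct = TRUE)) applied column-wise to a cells x features matrix.
rankSumTest <- function(x, inGroup) {
  x <- denseCounts(x)
  n1 <- sum(inGroup)
  n2 <- sum(!inGroup)
  n <- n1 + n2
  stats_w <- numeric(ncol(x))
  pvals <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    r <- rank(x[, j])
    W <- sum(r[inGroup]) - n1 * (n1 + 1) / 2
    ties <- table(x[, j])
    tie_term <- sum(ties^3 - ties)
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
    z <- W - n1 * n2 / 2
    corr <- sign(z) * 0.5
    z <- (z - corr) / sqrt(sigma2)
    stats_w[j] <- W
    pvals[j] <- if (sigma2 <= 0) 1 else min(1, 2 * pnorm(-abs(z)))
  }
  list(statistic = stats_w, p.value = pvals)
}

#' Supervised marker-based feature selection (Wilcoxon cascade)
#'
#' For each reference label, tests every feature with a Wilcoxon rank-sum
#' test (label vs rest) on log1p counts-per-10k values, then removes features
#' expressed (count > 0) in less than \code{minIn} of the label's cells,
#' expressed in more than \code{maxOut} of cells outside the label, or with
#' p-value above \code{pMax}. The survivors are sorted by estimated log2 fold
#' change (descending) and the top \code{nPerLabel} kept per label. Per-label
#' sets are combined by union (default) or intersection.
#'
#' @param ref a [CellMatrix-class] with at least 2 labels.
#' @param nPerLabel features kept per label after filtering (default 200).
#' @param minIn minimum expressing fraction within the label (default 0.10).
#' @param maxOut maximum expressing fraction outside the label (default 0.80).
#' @param pMax maximum (uncorrected) p-value (default 0.1).
#' @param combine "union" or "intersection" of the per-label sets.
#' @return a `SelectorResult`; scores are the best per-label log fold change.
#' @export
wilcoxonMarkers <- function(ref, nPerLabel = 200, minIn = 0.10, maxOut = 0.80,
                            pMax = 0.1, combine = c("union", "intersection")) {
  combine <- match.arg(combine)
  labels <- levels(droplevels(cellLabel(ref)))
  assertThat(length(labels) >= 2, "marker selection needs >= 2 labels")
  cts <- counts(ref)
  lognorm <- denseCounts(logNormalize(cts))
  ids <- featureIds(ref)
  per_label <- list()
  lfc_best <- setNames(rep(-Inf, length(ids)), ids)
  rank_best <- setNames(rep(Inf, length(ids)), ids)
  for (l in labels) {
    inGroup <- as.character(cellLabel(ref)) == l
    if (sum(inGroup) < 3) {
      warning("skipping label '", l, "' with fewer than 3 cells")
      next
    }
    frac_in <- Matrix::colMeans(cts[inGroup, , drop = FALSE] > 0)
    frac_out <- Matrix::colMeans(cts[!inGroup, , drop = FALSE] > 0)
    test <- rankSumTest(lognorm, inGroup)
    mean_in <- colMeans(lognorm[inGroup, , drop = FALSE])
    mean_out <- colMeans(lognorm[!inGroup, , drop = FALSE])
    lfc <- log2((expm1(mean_in) + 1e-9) / (expm1(mean_out) + 1e-9))
    keep <- frac_in >= minIn & frac_out <= maxOut & test$p.value <= pMax
    idx <- which(keep)
    idx <- idx[order(-lfc[idx])]
    idx <- head(idx, nPerLabel)
    per_label[[l]] <- ids[idx]
    if (length(idx)) {
      lfc_best[idx] <- pmax(lfc_best[idx], lfc[idx])
      rank_best[idx] <- pmin(rank_best[idx], seq_along(idx))
    }
  }
  assertThat(length(per_label) >= 1, "no label produced markers")
  feats <- if (combine == "union") {
    Reduce(union, per_label)
  } else {
    Reduce(intersect, per_label)
  }
  if (!length(feats)) {
    warning("marker combination ('", combine, "') produced an empty set")
    return(selectorResult("wilcoxon", character(), numeric(),
      nRequested = "auto"
    ))
  }
  # order by best within-label rank, then by fold change
  feats <- feats[order(rank_best[feats], -lfc_best[feats])]
  selectorResult("wilcoxon", feats, lfc_best[feats], nRequested = "auto")
}
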