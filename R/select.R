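#' @title Feature selector result
#' @description A lightweight record returned by the selectors: the chosen
#'   features most-informative-first, the per-feature statistic used for
#'   ranking, and bookkeeping fields.
#' @name SelectorResult
NULL

selectorResult <- function(method, features, scores, nRequested,
                           batchAware = FALSE, seed = NULL) {
  stopifnot(!anyDuplicated(features))
  res <- list(
    method = method, features = features, scores = scores,
    nRequested = nRequested, batchAware = batchAware, seed = seed
  )
  class(res) <- c("SelectorResult", "list")
  res
}

#' @export
print.SelectorResult <- function(x, ...) {
  cat(
    "SelectorResult:", x$method, if (x$batchAware) "(batch-aware)" else "",
    "|", length(x$features), "features\n"
  )
  invisible(x)
}

simpleSelectorMethods <- c(
  "all", "random", "high_mean", "high_variance",
  "hvg_binned_dispersion", "hvg_vst"
)

#' Simple feature selectors
#'
#' Rank and select features from the reference with one of the simple
#' strategies: every feature, uniform random sets, highest raw mean or
#' variance, dispersion-based highly variable genes (normalise to counts per
#' 10k, log1p, dispersion = variance/mean, z-scored within 20 mean bins), or
#' a variance-stabilising-transform style ranking (degree-2 polynomial trend
#' of log10 variance on log10 mean of raw counts; variance of standardised
#' counts clipped at sqrt(n_cells)).
#'
#' @param ref a [CellMatrix-class] (the reference half).
#' @param method one of `r paste0('"', simpleSelectorMethods, '"', collapse = ", ")`.
#' @param n number of features to select (ignored for "all"); default 2000.
#' @param seed seed for the "random" method.
#' @return a `SelectorResult`.
#' @export
selectFeatures <- function(ref, method = simpleSelectorMethods, n = 2000,
                           seed = NULL) {
  method <- match.arg(method)
  ids <- featureIds(ref)
  if (method != "all") {
    assertThat(
      n <= length(ids),
      "n = ", n, " exceeds the number of features (", length(ids), ")"
    )
  }
  cts <- counts(ref)
  switch(method,
    all = selectorResult("all", ids, setNames(rep(1, length(ids)), ids),
      nRequested = "auto"
    ),
    random = withSeed(seed, {
      feats <- sample(ids, n)
      selectorResult("random", feats,
        setNames(rep(NA_real_, n), feats),
        nRequested = n, seed = seed
      )
    }),
    high_mean = {
      s <- setNames(as.numeric(Matrix::colMeans(cts)), ids)
      ord <- order(-s, seq_along(s))
      selectorResult("high_mean", ids[ord][seq_len(n)], s[ord][seq_len(n)],
        nRequested = n
      )
    },
    high_variance = {
      s <- setNames(colVars(cts), ids)
      assertThat(any(s > 0), "all features have zero variance")
      ord <- order(-s, seq_along(s))
      selectorResult("high_variance", ids[ord][seq_len(n)], s[ord][seq_len(n)],
        nRequested = n
      )
    },
    hvg_binned_dispersion = {
      s <- binnedDispersionScores(cts)
      ord <- order(-s, seq_along(s))
      selectorResult("hvg_binned_dispersion", ids[ord][seq_len(n)],
        s[ord][seq_len(n)],
        nRequested = n
      )
    },
    hvg_vst = {
      s <- vstScores(cts)
      ord <- order(-s, seq_along(s))
      selectorResult("hvg_vst", ids[ord][seq_len(n)], s[ord][seq_len(n)],
        nRequested = n
      )
    }
  )
}

binnedDispersionScores <- function(cts, nBins = 20) {
  x <- denseCounts(logNormalize(cts))
  mu <- colMeans(x)
  v <- matrixStats::colVars(x)
  disp <- ifelse(mu > 0, v / mu, 0)
  assertThat(any(disp > 0), "all features have zero dispersion")
  bins <- cut(mu, breaks = nBins, include.lowest = TRUE)
  z <- disp
  for (b in levels(bins)) {
    idx <- which(bins == b)
    if (length(idx) < 2) {
      z[idx] <- 0
      next
    }
    s <- sd(disp[idx])
    z[idx] <- if (is.na(s) || s == 0) 0 else (disp[idx] - mean(disp[idx])) / s
  }
  setNames(z, colnames(cts))
}

vstScores <- function(cts) {
  x <- denseCounts(cts)
  n <- nrow(x)
  mu <- colMeans(x)
  v <- matrixStats::colVars(x)
  assertThat(any(v > 0), "all features have zero variance")
  usable <- v > 0 & mu > 0
  fit <- lm(log10(v[usable]) ~ poly(log10(mu[usable]), 2))
  exp_sd <- rep(NA_real_, length(mu))
  exp_sd[usable] <- sqrt(10^predict(fit))
  clip <- sqrt(n)
  score <- rep(0, length(mu))
  for (j in which(usable)) {
    z <- pmin((x[, j] - mu[j]) / exp_sd[j], clip)
    score[j] <- sum((z - mean(z))^2) / (n - 1)
  }
  setNames(score, colnames(x))
}

#' Batch-aware feature selection
#'
#' Runs a simple selector separately within each batch and combines the
#' per-batch sets by the number of batches selecting each feature
#' (descending), breaking ties by the median within-batch rank (ascending).
#' Batches with fewer than 2 cells are skipped with a warning.
#'
#' @inheritParams selectFeatures
#' @return a `SelectorResult` with `batchAware = TRUE`.
#' @export
selectBatchAware <- function(ref, method = simpleSelectorMethods, n = 2000,
                             seed = NULL) {
  method <- match.arg(method)
  batches <- levels(droplevels(cellBatch(ref)))
  assertThat(length(batches) >= 2, "batch-aware selection needs >= 2 batches")
  ids <- featureIds(ref)
  rank_mat <- matrix(NA_real_, length(ids), 0, dimnames = list(ids, NULL))
  used <- 0L
  for (b in batches) {
    idx <- which(as.character(cellBatch(ref)) == b)
    if (length(idx) < 2) {
      warning("skipping batch '", b, "' with fewer than 2 cells")
      next
    }
    sub <- ref[idx, ]
    res <- selectFeatures(sub, method, n = min(n, length(ids)), seed = seed)
    r <- rep(NA_real_, length(ids))
    r[match(res$features, ids)] <- seq_along(res$features)
    rank_mat <- cbind(rank_mat, r)
    used <- used + 1L
  }
  assertThat(used >= 1, "no usable batches")
  n_sel <- rowSums(!is.na(rank_mat))
  med_rank <- apply(rank_mat, 1, function(r) {
    if (all(is.na(r))) Inf else stats::median(r, na.rm = TRUE)
  })
  ord <- order(-n_sel, med_rank, seq_along(ids))
  keep <- ord[n_sel[ord] > 0]
  keep <- keep[seq_len(min(n, length(keep)))]
  selectorResult(method, ids[keep],
    setNames(n_sel[keep], ids[keep]),
    nRequested = n, batchAware = TRUE, seed = seed
  )
}
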