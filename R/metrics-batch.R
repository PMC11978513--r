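# Integration (Batch) metrics: LISI family, batch principal-component
# regression, and the cell-specific mixing score.

# Perplexity-calibrated Gaussian kernel weights over the 3*perplexity nearest
# neighbours (squared-distance Gaussian, bandwidth solved per cell so the
# weight entropy matches log(perplexity)), then Simpson's index of the
# grouping probabilities. Returns the per-cell inverse Simpson index.
perCellLISI <- function(coords, grouping, perplexity = 30) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  grouping <- factor(grouping)
  k <- floor(3 * perplexity)
  if (k > n - 1) {
    perplexity <- max(1, (n - 1) / 3)
    k <- n - 1L
    warning("fewer cells than the perplexity window; perplexity reduced to ",
      signif(perplexity, 3))
  }
  nn <- knnSearch(coords, k)
  logU <- log(perplexity)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- nn$dist[i, ]^2
    beta <- 1
    lo <- -Inf
    hi <- Inf
    for (iter in 1:128) {
      w <- exp(-beta * d2)
      sw <- sum(w)
      if (sw == 0) {
        h <- 0
      } else {
        p <- w / sw
        h <- -sum(ifelse(p > 0, p * log(p), 0))
      }
      diff <- h - logU
      if (abs(diff) < 1e-12) break
      if (diff > 0) { # entropy too high -> narrow the kernel
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    w <- exp(-beta * d2)
    if (sum(w) == 0) {
      w <- rep(1, length(d2))
    }
    p <- w / sum(w)
    pg <- tapply(p, grouping[nn$index[i, ]], sum, default = 0)
    lambda <- sum(pg^2)
    vals[i] <- 1 / lambda
  }
  vals
}

#' Local inverse Simpson's index scores
#'
#' Per-cell inverse Simpson's index of a grouping within perplexity-weighted
#' Gaussian neighbourhoods, averaged over cells and rescaled to \[0, 1\].
#' Mixing modes (\code{ilisi}: reference batches; \code{mlisi}:
#' reference-vs-query origin over all cells; \code{qlisi}: query batches over
#' query cells) rescale as (LISI - 1) / (G - 1) so 1 means perfect mixing.
#' The separation mode (\code{clisi}: reference labels) rescales as
#' (G - LISI) / (G - 1) so 1 means perfectly separated labels.
#'
#' @param coords coordinate matrix of the cells the mode applies to.
#' @param grouping per-cell grouping factor (batch, label or origin).
#' @param mode one of "ilisi", "clisi", "mlisi", "qlisi".
#' @param cfg a [metricConfig()].
#' @return a `MetricScore`.
#' @export
lisiScore <- function(coords, grouping, mode = c("ilisi", "clisi", "mlisi", "qlisi"),
                      cfg = metricConfig()) {
  mode <- match.arg(mode)
  grouping <- droplevels(factor(grouping))
  G <- nlevels(grouping)
  category <- switch(mode,
    ilisi = "batch", clisi = "bio", mlisi = "mapping", qlisi = "mapping"
  )
  if (G < 2) {
    if (mode == "clisi") {
      warning("single label: cLISI set to 1")
      return(metricScore("clisi", "bio", 1, nrow(coords), "single group"))
    }
    stop("LISI mixing modes need at least 2 groups", call. = FALSE)
  }
  lisi <- mean(perCellLISI(coords, grouping, cfg$lisiPerplexity))
  value <- if (mode == "clisi") {
    (G - lisi) / (G - 1)
  } else {
    (lisi - 1) / (G - 1)
  }
  metricScore(mode, category, min(max(value, 0), 1), nrow(coords))
}

# Variance-weighted fraction of embedding variance explained by batch:
# PCs of x are regressed on the batch factor, R^2 weighted by PC variance.
pcRegression <- function(x, batch, nComps = 50) {
  x <- as.matrix(x)
  nComps <- min(nComps, ncol(x), nrow(x) - 1L)
  pca <- prcomp(x, rank. = nComps, center = TRUE, scale. = FALSE)
  vars <- pca$sdev[seq_len(nComps)]^2
  keep <- vars > 1e-12
  if (!any(keep)) {
    return(0)
  }
  batch <- droplevels(factor(batch))
  r2 <- vapply(which(keep), function(j) {
    pc <- pca$x[, j]
    sst <- sum((pc - mean(pc))^2)
    means <- tapply(pc, batch, mean)
    ssb <- sum(table(batch) * (means - mean(pc))^2)
    ssb / sst
  }, numeric(1))
  sum(vars[keep] * r2) / sum(vars[keep])
}

#' Batch principal-component regression score
#'
#' Measures residual batch effect as the variance-weighted R^2 of embedding
#' principal components regressed on batch. With a pre-integration embedding
#' the score is the fraction of batch variance removed,
#' clip((PCR_pre - PCR_post) / PCR_pre, 0, 1); without one it falls back to
#' 1 - PCR_post.
#'
#' @param emb a [JointEmbedding-class] (reference rows are used).
#' @param batch reference batch factor.
#' @param nComps number of principal components (default 50).
#' @param cfg a [metricConfig()].
#' @return a `MetricScore` in the batch category.
#' @export
batchPCR <- function(emb, batch, nComps = 50, cfg = metricConfig()) {
  x_post <- refCoords(emb)
  assertThat(nlevels(droplevels(factor(batch))) >= 2, "need >= 2 batches")
  pcr_post <- pcRegression(x_post, batch, nComps)
  pre <- preIntegration(emb)
  if (!is.null(pre)) {
    x_pre <- pre[seq_len(nrow(x_post)), , drop = FALSE]
    pcr_pre <- pcRegression(x_pre, batch, nComps)
    if (pcr_pre <= 1e-12) {
      warning("pre-integration batch variance is zero; score set to 1")
      return(metricScore("batch_pcr", "batch", 1, nrow(x_post),
        "nothing to remove"))
    }
    value <- min(max((pcr_pre - pcr_post) / pcr_pre, 0), 1)
  } else {
    value <- 1 - pcr_post
  }
  metricScore("batch_pcr", "batch", value, nrow(x_post))
}

# ---- Anderson-Darling k-sample test (Scholz & Stephens 1987, version 1) ----

adKSampleStatistic <- function(groups) {
  ni <- lengths(groups)
  k <- length(groups)
  N <- sum(ni)
  pooled <- unlist(groups, use.names = FALSE)
  sample_id <- rep(seq_len(k), ni)
  ord <- order(pooled)
  sample_sorted <- sample_id[ord]
  A2 <- 0
  js <- seq_len(N - 1)
  denom <- js * (N - js)
  for (i in seq_len(k)) {
    Mij <- cumsum(sample_sorted == i)[js]
    A2 <- A2 + sum((N * Mij - js * ni[i])^2 / denom) / ni[i]
  }
  A2 / N
}

adKSamplePValue <- function(A2, ni) {
  k <- length(ni)
  N <- sum(ni)
  H <- sum(1 / ni)
  h <- sum(1 / seq_len(N - 1))
  ivals <- seq_len(N - 2)
  g <- sum(vapply(ivals, function(i) {
    sum(1 / ((N - i) * seq(i + 1, N - 1)))
  }, numeric(1)))
  a <- (4 * g - 6) * (k - 1) + (10 - 6 * g) * H
  b <- (2 * g - 4) * k^2 + 8 * h * k + (2 * g - 14 * h - 4) * H - 8 * h + 4 * g - 6
  cc <- (6 * h + 2 * g - 2) * k^2 + (4 * h - 4 * g + 6) * k + (2 * h - 6) * H + 4 * h
  d <- (2 * h + 6) * k^2 - 4 * h * k
  var_A2 <- (a * N^3 + b * N^2 + cc * N + d) /
    ((N - 1) * (N - 2) * (N - 3))
  if (var_A2 <= 0) {
    return(1)
  }
  T_obs <- (A2 - (k - 1)) / sqrt(var_A2)
  m <- k - 1
  alphas <- c(0.25, 0.10, 0.05, 0.025, 0.01)
  b0 <- c(0.675, 1.281, 1.645, 1.960, 2.326)
  b1 <- c(-0.245, 0.250, 0.678, 1.149, 1.822)
  b2 <- c(-0.105, -0.305, -0.362, -0.391, -0.396)
  tm <- b0 + b1 / sqrt(m) + b2 / m
  lp <- log(alphas / (1 - alphas))
  # interpolate log-odds of the p-value in the standardized statistic
  if (T_obs <= tm[1]) {
    slope <- (lp[2] - lp[1]) / (tm[2] - tm[1])
    lpv <- lp[1] + slope * (T_obs - tm[1])
  } else if (T_obs >= tm[5]) {
    slope <- (lp[5] - lp[4]) / (tm[5] - tm[4])
    lpv <- lp[5] + slope * (T_obs - tm[5])
  } else {
    f <- stats::splinefun(tm, lp, method = "natural")
    lpv <- f(T_obs)
  }
  1 / (1 + exp(-lpv))
}

# k-sample Anderson-Darling test; returns the asymptotic p-value.
adKSampleTest <- function(groups) {
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) {
    return(NA_real_)
  }
  A2 <- adKSampleStatistic(groups)
  adKSamplePValue(A2, lengths(groups))
}

#' Cell-specific mixing score
#'
#' For every reference cell, tests whether the distances to its k nearest
#' neighbours follow the same distribution in each batch (Anderson-Darling
#' k-sample test on neighbour distances grouped by the neighbour's batch;
#' batch groups with fewer than 5 members are dropped, and cells with fewer
#' than 2 usable groups get p = 0). The score is 1 minus the proportion of
#' cells with p below \code{cmsAlpha}, so 1 means batches are locally
#' indistinguishable.
#'
#' @param coords reference coordinate matrix.
#' @param batch reference batch factor.
#' @param cfg a [metricConfig()].
#' @return a `MetricScore` in the batch category.
#' @export
cmsScore <- function(coords, batch, cfg = metricConfig()) {
  coords <- as.matrix(coords)
  batch <- droplevels(factor(batch))
  assertThat(nlevels(batch) >= 2, "CMS needs >= 2 batches")
  n <- nrow(coords)
  k <- cfg$cmsK
  if (k >= n) {
    k <- n - 1L
    warning("cmsK reduced to n - 1 = ", k)
  }
  nn <- knnSearch(coords, k)
  pvals <- numeric(n)
  for (i in seq_len(n)) {
    groups <- split(nn$dist[i, ], batch[nn$index[i, ]])
    groups <- groups[lengths(groups) >= 5]
    pvals[i] <- if (length(groups) < 2) 0 else adKSampleTest(groups)
  }
  value <- 1 - mean(pvals < cfg$cmsAlpha)
  metricScore("cms", "batch", value, n)
}
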