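# Independent brute-force oracle implementations used by the unit and
# acceptance tests. Each solves the same quantity as the package from first
# principles (dense distances, explicit root finding, direct counting) so
# agreement is a genuine cross-check, not a reimplementation call.

# LISI: dense distance matrix, kernel bandwidth solved by uniroot on the
# entropy equation, Simpson's index from the explicit weights.
bruteLISI <- function(coords, grouping, perplexity) {
  n <- nrow(coords)
  k <- min(floor(3 * perplexity), n - 1)
  D <- as.matrix(dist(coords))
  grouping <- factor(grouping)
  vapply(seq_len(n), function(i) {
    ord <- order(D[i, -i])
    nbr <- setdiff(seq_len(n), i)[ord][seq_len(k)]
    d2 <- D[i, nbr]^2
    entropy <- function(beta) {
      w <- exp(-beta * d2)
      p <- w / sum(w)
      -sum(ifelse(p > 0, p * log(p), 0)) - log(perplexity)
    }
    lo <- 1e-12
    hi <- 1
    while (entropy(hi) > 0 && hi < 1e12) hi <- hi * 10
    beta <- uniroot(entropy, c(lo, hi), tol = 1e-14)$root
    w <- exp(-beta * d2)
    p <- w / sum(w)
    pg <- tapply(p, grouping[nbr], sum, default = 0)
    1 / sum(pg^2)
  }, numeric(1))
}

# Plain (unweighted) NMI with arithmetic-mean normalisation.
plainNMI <- function(a, b) {
  a <- factor(a)
  b <- factor(b)
  joint <- table(a, b) / length(a)
  pr <- rowSums(joint)
  pc <- colSums(joint)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / (pr[row(joint)[nz]] * pc[col(joint)[nz]])))
  hr <- -sum(ifelse(pr > 0, pr * log(pr), 0))
  hc <- -sum(ifelse(pc > 0, pc * log(pc), 0))
  mi / ((hr + hc) / 2)
}

# Largest-component fraction of a label's kNN subgraph via union-find over
# the same neighbour lists the package uses.
unionFindConnectivity <- function(coords, labels, k) {
  nn <- scMapBench:::knnSearch(coords, k)
  perLabel <- vapply(unique(labels), function(l) {
    idx <- which(labels == l)
    if (length(idx) <= 1) {
      return(1)
    }
    parent <- seq_along(idx)
    find <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    pos <- match(seq_len(nrow(coords)), idx)
    link <- function(i, j) {
      ri <- find(i)
      rj <- find(j)
      if (ri != rj) parent[ri] <<- rj
    }
    for (i in seq_along(idx)) {
      for (j in nn$index[idx[i], ]) {
        if (!is.na(pos[j])) link(i, pos[j])
      }
    }
    roots <- vapply(seq_along(idx), find, integer(1))
    max(table(roots)) / length(idx)
  }, numeric(1))
  mean(perLabel)
}

# Spearman correlation as Pearson on midranks, written out longhand.
bruteSpearman <- function(a, b) {
  ra <- rank(a)
  rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}
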