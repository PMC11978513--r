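#' @import methods
#' @importClassesFrom Matrix Matrix
#' @importFrom stats rnorm runif rgamma rpois rlnorm sd var cor quantile
#'   prcomp p.adjust pnorm binom.test complete.cases aggregate setNames
#'   predict lm poly coef mahalanobis cov
#' @importFrom utils head read.delim write.table
NULL

# Evaluate expr with a temporarily fixed RNG state, restoring the caller's
# stream afterwards so seeded helpers do not perturb user code.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        },
        add = TRUE
      )
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic per-string score in [0,1], mixed with a seed. Used for
# subsampling keyed on cell identifiers so results do not depend on row order.
stableHash <- function(ids, seed = 0L) {
  seed <- as.integer(seed) %% 2147483647L
  vapply(ids, function(id) {
    h <- 5381
    for (v in utf8ToInt(as.character(id))) {
      h <- (h * 33 + v) %% 2147483647
    }
    h <- (h * 2654435761 + seed * 97 + 1) %% 2147483647
    # one more scramble round to decorrelate consecutive ids
    h <- (h * 48271) %% 2147483647
    h / 2147483647
  }, numeric(1), USE.NAMES = FALSE)
}

# k nearest neighbours (excluding self) of `query` rows among `data` rows.
# Returns list(index, dist) with rows sorted by ascending distance.
knnSearch <- function(data, k, query = NULL) {
  data <- as.matrix(data)
  if (is.null(query)) {
    k <- min(k, nrow(data) - 1L)
    res <- FNN::get.knn(data, k = k)
    list(index = res$nn.index, dist = res$nn.dist, k = k)
  } else {
    k <- min(k, nrow(data))
    res <- FNN::get.knnx(data, as.matrix(query), k = k)
    list(index = res$nn.index, dist = res$nn.dist, k = k)
  }
}

# Library-size normalisation to counts-per-`scale` followed by log1p.
# Accepts dense or sparse cells x features counts; returns same orientation.
logNormalize <- function(counts, scale = 1e4) {
  totals <- Matrix::rowSums(counts)
  totals[totals == 0] <- 1
  norm <- counts / totals * scale
  if (inherits(norm, "sparseMatrix")) {
    norm@x <- log1p(norm@x)
    norm
  } else {
    log1p(as.matrix(norm))
  }
}

denseCounts <- function(counts) {
  if (inherits(counts, "sparseMatrix")) as.matrix(counts) else counts
}

# Shrunk covariance (Sigma + eps * mean diag * I) with cached Cholesky-based
# Mahalanobis distances; pseudo-inverse when rank deficient.
shrunkCovariance <- function(x, eps = 1e-6) {
  x <- as.matrix(x)
  d <- ncol(x)
  mu <- colMeans(x)
  if (nrow(x) < 2) {
    sigma <- diag(1, d)
  } else {
    sigma <- cov(x)
  }
  tr <- sum(diag(sigma))
  if (!is.finite(tr) || tr <= 0) tr <- d
  sigma <- sigma + eps * (tr / d) * diag(d)
  inv <- tryCatch(chol2inv(chol(sigma)), error = function(e) {
    MASS::ginv(sigma)
  })
  list(mean = mu, sigma = sigma, inv = inv)
}

mahalanobisDist <- function(x, fit) {
  x <- as.matrix(x)
  delta <- sweep(x, 2, fit$mean)
  sqrt(pmax(rowSums((delta %*% fit$inv) * delta), 0))
}

colVars <- function(x) {
  if (inherits(x, "sparseMatrix")) {
    n <- nrow(x)
    mu <- Matrix::colMeans(x)
    (Matrix::colMeans(x^2) - mu^2) * n / (n - 1)
  } else {
    matrixStats::colVars(as.matrix(x))
  }
}

assertThat <- function(ok, ...) {
  if (!ok) stop(..., call. = FALSE)
}
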