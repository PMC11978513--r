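#' Metric configuration
#'
#' Collects the tunable parameters shared by the benchmark metrics.
#'
#' @param lisiPerplexity perplexity of the Gaussian neighbourhood kernel used
#'   by the LISI family (default 30; neighbourhood size is 3x perplexity).
#' @param knnKGraph neighbours for the kNN graph behind clustering, graph
#'   connectivity and density estimates (default 90).
#' @param cmsK neighbours per cell for the cell-specific mixing score
#'   (default 75).
#' @param cmsAlpha p-value threshold counted by CMS (default 0.1).
#' @param cellDistQuantile reference quantile defining the cell distance
#'   boundary (default 0.90).
#' @param labelMinQueryCells labels with fewer query cells are skipped by the
#'   label distance metrics (default 20).
#' @param knnCorrK neighbours for the kNN correlation metric (default 100).
#' @param miloFdr FDR threshold for significant neighbourhoods (default 0.1).
#' @param miloKPerBatch,miloKMax neighbourhood size rule: k = miloKPerBatch x
#'   n_batches capped at miloKMax (defaults 5 and 200).
#' @param miloSubsetMin,miloSubsetFrac index cells subsampled up to
#'   max(miloSubsetMin, miloSubsetFrac x n_cells) (defaults 20000 and 0.1).
#' @param leidenResolutions resolutions swept by the clustering-based
#'   metrics (default 0.1 to 2.0 in steps of 0.1).
#' @param covShrinkageEps covariance shrinkage epsilon for Mahalanobis
#'   distances (default 1e-6).
#' @param ldfBound upper bound u on absolute log2 local density factor
#'   differences (default 1.0).
#' @param seed seed for the metrics' stochastic steps (subsampling,
#'   clustering initialisation).
#' @return a \code{MetricConfig} list.
#' @export
metricConfig <- function(lisiPerplexity = 30, knnKGraph = 90, cmsK = 75,
                         cmsAlpha = 0.1, cellDistQuantile = 0.90,
                         labelMinQueryCells = 20, knnCorrK = 100,
                         miloFdr = 0.1, miloKPerBatch = 5, miloKMax = 200,
                         miloSubsetMin = 20000, miloSubsetFrac = 0.1,
                         leidenResolutions = seq(0.1, 2.0, by = 0.1),
                         covShrinkageEps = 1e-6, ldfBound = 1.0, seed = 1L) {
  assertThat(
    lisiPerplexity > 0 && knnKGraph > 0 && cmsK > 0 && knnCorrK > 0,
    "neighbourhood sizes must be positive"
  )
  assertThat(
    cmsAlpha > 0 && cmsAlpha < 1 && miloFdr > 0 && miloFdr < 1,
    "cmsAlpha and miloFdr must be in (0, 1)"
  )
  assertThat(
    cellDistQuantile > 0 && cellDistQuantile < 1,
    "cellDistQuantile must be in (0, 1)"
  )
  cfg <- list(
    lisiPerplexity = lisiPerplexity, knnKGraph = knnKGraph, cmsK = cmsK,
    cmsAlpha = cmsAlpha, cellDistQuantile = cellDistQuantile,
    labelMinQueryCells = labelMinQueryCells, knnCorrK = knnCorrK,
    miloFdr = miloFdr, miloKPerBatch = miloKPerBatch, miloKMax = miloKMax,
    miloSubsetMin = miloSubsetMin, miloSubsetFrac = miloSubsetFrac,
    leidenResolutions = leidenResolutions,
    covShrinkageEps = covShrinkageEps, ldfBound = ldfBound,
    seed = as.integer(seed)
  )
  class(cfg) <- c("MetricConfig", "list")
  cfg
}

metricScore <- function(name, category, value, nCellsUsed = NA_integer_,
                        notes = character()) {
  assertThat(category %in% metricCategories, "unknown category: ", category)
  res <- list(
    name = name, category = category, value = as.numeric(value),
    nCellsUsed = nCellsUsed, notes = notes
  )
  class(res) <- c("MetricScore", "list")
  res
}

#' @export
print.MetricScore <- function(x, ...) {
  cat(sprintf(
    "MetricScore %s [%s] = %.4f (n = %s)\n", x$name, x$category,
    x$value, x$nCellsUsed
  ))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
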