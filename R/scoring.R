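# Baseline-anchored scaling, category aggregation, overall score, ranking,
# standardisation and metric profiling.

optionalMetrics <- c("knn_correlation", "unseen_uncertainty")

#' Scale raw metric scores against baseline ranges
#'
#' For each (dataset, metric) pair, the minimum and maximum scores of the
#' baseline methods define an effective range and every raw score is rescaled
#' as (raw - min) / (max - min). Values outside \[0, 1\] are possible (a
#' method beating or trailing every baseline) and are deliberately not
#' clipped. A degenerate baseline range (max == min) yields a missing scaled
#' value with a warning.
#'
#' @param raw score table of the methods under evaluation.
#' @param baselines score table of the baseline methods (same format; the
#'   four bundled baselines are all features, batch-aware dispersion HVGs at
#'   n = 2000, random n = 500 averaged over five seeds, and the stable
#'   lowest-variance n = 200 negative control).
#' @return the raw table with columns \code{raw_value} (input) and
#'   \code{value} (scaled).
#' @export
scaleScores <- function(raw, baselines) {
  validateScoreTable(raw)
  validateScoreTable(baselines)
  out <- raw
  out$raw_value <- raw$value
  out$value <- NA_real_
  for (i in seq_len(nrow(out))) {
    b <- baselines$value[
      baselines$dataset == out$dataset[i] & baselines$metric == out$metric[i]
    ]
    b <- b[is.finite(b)]
    if (!length(b)) {
      warning(
        "no baseline scores for ", out$dataset[i], "/", out$metric[i]
      )
      next
    }
    lo <- min(b)
    hi <- max(b)
    if (hi - lo <= 0) {
      warning(
        "degenerate baseline range for ", out$dataset[i], "/",
        out$metric[i], "; scaled value undefined"
      )
      next
    }
    out$value[i] <- (out$raw_value[i] - lo) / (hi - lo)
  }
  out
}

#' Aggregate scaled scores into category and overall summaries
#'
#' Category scores are the mean of each category's scaled metrics (missing
#' values excluded). The overall score follows the weighted mean
#' \deqn{Overall = \frac{1}{2}(\frac{Int.Batch}{2} + \frac{Int.Bio}{2}) +
#'   \frac{1}{2}(\frac{Mapping}{3} + \frac{Class.}{3} + \frac{Unseen}{3})}
#' i.e. weights (1/4, 1/4, 1/6, 1/6, 1/6). Optional metrics (kNN
#' correlation, unseen uncertainty) never enter category means unless
#' remapped via \code{categoryMap}.
#'
#' @param scaled scaled score table ([scaleScores()] output or any table
#'   with dataset/method/metric/category/value).
#' @param categoryMap optional named character vector metric -> category
#'   overriding the default assignment.
#' @return data frame with one row per (dataset, method): category means
#'   \code{int_batch}, \code{int_bio}, \code{mapping}, \code{classification},
#'   \code{unseen} and \code{overall}.
#' @export
aggregateScores <- function(scaled, categoryMap = NULL) {
  validateScoreTable(scaled)
  tab <- scaled
  if (!is.null(categoryMap)) {
    hit <- tab$metric %in% names(categoryMap)
    tab$category[hit] <- unname(categoryMap[tab$metric[hit]])
  } else {
    tab <- tab[!(tab$metric %in% optionalMetrics), , drop = FALSE]
  }
  combos <- unique(tab[, c("dataset", "method")])
  res <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- tab[
      tab$dataset == combos$dataset[i] & tab$method == combos$method[i], ,
      drop = FALSE
    ]
    cat_mean <- vapply(metricCategories, function(cc) {
      v <- sub$value[sub$category == cc]
      v <- v[is.finite(v)]
      if (!length(v)) NA_real_ else mean(v)
    }, numeric(1))
    if (any(is.na(cat_mean))) {
      stop(
        "category without any metric score for ", combos$dataset[i], "/",
        combos$method[i], ": ",
        paste(metricCategories[is.na(cat_mean)], collapse = ", "),
        call. = FALSE
      )
    }
    data.frame(
      dataset = combos$dataset[i], method = combos$method[i],
      int_batch = cat_mean[["batch"]], int_bio = cat_mean[["bio"]],
      mapping = cat_mean[["mapping"]],
      classification = cat_mean[["classification"]],
      unseen = cat_mean[["unseen"]],
      overall = overallScore(cat_mean),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}

# Weighted mean of the five category scores: (1/4, 1/4, 1/6, 1/6, 1/6).
overallScore <- function(cat_mean) {
  0.5 * (cat_mean[["batch"]] / 2 + cat_mean[["bio"]] / 2) +
    0.5 * (cat_mean[["mapping"]] / 3 + cat_mean[["classification"]] / 3 +
      cat_mean[["unseen"]] / 3)
}

#' Rank methods within and across datasets
#'
#' Ranks descending by score within each dataset at each level (overall and
#' the five categories); ties receive the average rank. Cross-dataset ranks
#' are the mean of per-dataset ranks, reported with their standard
#' deviation. Method-dataset cells missing from the summary are excluded
#' from that dataset's ranking.
#'
#' @param summaries output of [aggregateScores()] across >= 2 methods.
#' @param levels summary columns to rank (default overall + categories).
#' @return list with \code{perDataset} (long data frame dataset / level /
#'   method / score / rank) and \code{crossDataset} (method / level /
#'   mean_rank / sd_rank).
#' @export
rankMethods <- function(summaries,
                        levels = c(
                          "overall", "int_batch", "int_bio", "mapping",
                          "classification", "unseen"
                        )) {
  assertThat(
    length(unique(summaries$method)) >= 2,
    "ranking needs >= 2 methods"
  )
  per <- list()
  for (ds in unique(summaries$dataset)) {
    sub <- summaries[summaries$dataset == ds, , drop = FALSE]
    for (lv in levels) {
      ok <- is.finite(sub[[lv]])
      r <- rank(-sub[[lv]][ok], ties.method = "average")
      per[[length(per) + 1L]] <- data.frame(
        dataset = ds, level = lv, method = sub$method[ok],
        score = sub[[lv]][ok], rank = r, stringsAsFactors = FALSE
      )
    }
  }
  per <- do.call(rbind, per)
  agg <- aggregate(rank ~ method + level, per, function(x) {
    c(mean = mean(x), sd = if (length(x) > 1) sd(x) else 0)
  })
  cross <- data.frame(
    method = agg$method, level = agg$level,
    mean_rank = agg$rank[, "mean"], sd_rank = agg$rank[, "sd"],
    stringsAsFactors = FALSE
  )
  list(perDataset = per, crossDataset = cross)
}

#' Standardise scores within groups (z-scores)
#'
#' z = (x - group mean) / group sd with the sample (n - 1) standard
#' deviation; constant groups get z = 0.
#'
#' @param df data frame of scores.
#' @param by character vector of grouping columns (default dataset and
#'   method).
#' @param value column to standardise.
#' @return \code{df} with an added column \code{z}.
#' @export
standardizeScores <- function(df, by = c("dataset", "method"),
                              value = "value") {
  key <- interaction(df[by], drop = TRUE)
  z <- numeric(nrow(df))
  for (g in levels(key)) {
    idx <- which(key == g)
    x <- df[[value]][idx]
    s <- sd(x)
    z[idx] <- if (is.na(s) || s == 0) 0 else (x - mean(x)) / s
  }
  df$z <- z
  df
}

#' Profile metric behaviour across feature-set sizes
#'
#' Characterises each metric from score tables computed on random feature
#' sets (for the observed dynamic range) and on ordered, e.g. HVG-ranked,
#' sets of increasing size (for the correlation with the number of selected
#' features). Also reports correlations with supplied technical dataset
#' factors and the full inter-metric Pearson correlation matrix. Metrics
#' whose observed range is (near) zero cannot distinguish feature sets and
#' are exclusion candidates.
#'
#' @param scores data frame with columns metric, dataset, value,
#'   n_features and set_type ("random" or "ordered").
#' @param technical optional data frame keyed by dataset with numeric
#'   technical factor columns.
#' @return list with \code{perMetric} (metric / observed_range /
#'   cor_n_features and one cor_<factor> column per technical factor) and
#'   \code{interMetric} (correlation matrix).
#' @export
profileMetrics <- function(scores, technical = NULL) {
  metrics <- unique(scores$metric)
  per <- lapply(metrics, function(m) {
    sub <- scores[scores$metric == m, , drop = FALSE]
    rnd <- sub[sub$set_type == "random", , drop = FALSE]
    rng <- if (nrow(rnd)) {
      mean(tapply(rnd$value, rnd$dataset, function(v) {
        diff(range(v[is.finite(v)]))
      }), na.rm = TRUE)
    } else {
      NA_real_
    }
    ordd <- sub[sub$set_type == "ordered", , drop = FALSE]
    cor_n <- if (nrow(ordd) >= 3 && sd(ordd$value) > 0 &&
      sd(ordd$n_features) > 0) {
      cor(ordd$n_features, ordd$value)
    } else {
      NA_real_
    }
    row <- data.frame(
      metric = m, observed_range = rng, cor_n_features = cor_n,
      stringsAsFactors = FALSE
    )
    if (!is.null(technical)) {
      merged <- merge(rnd, technical, by = "dataset")
      for (fac in setdiff(colnames(technical), "dataset")) {
        cc <- if (nrow(merged) >= 3 && sd(merged$value) > 0 &&
          sd(merged[[fac]]) > 0) {
          cor(merged$value, merged[[fac]])
        } else {
          NA_real_
        }
        row[[paste0("cor_", fac)]] <- cc
      }
    }
    row
  })
  per <- do.call(rbind, per)
  # inter-metric correlations over shared (dataset, set) observations
  scores$set_id <- interaction(
    scores$dataset, scores$set_type, scores$n_features,
    if (!is.null(scores$set_seed)) scores$set_seed else 0,
    drop = TRUE
  )
  wide <- tapply(scores$value, list(scores$set_id, scores$metric), mean)
  keep <- colSums(!is.na(wide)) > 2
  inter <- suppressWarnings(
    cor(wide[, keep, drop = FALSE], use = "pairwise.complete.obs")
  )
  list(perMetric = per, interMetric = inter)
}
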