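# Baseline scaling, aggregation, overall score, ranking, standardisation
# and metric profiling.

scoreRow <- function(dataset, method, metric, category, value) {
  data.frame(
    dataset = dataset, method = method, metric = metric,
    category = category, value = value, stringsAsFactors = FALSE
  )
}

test_that("baseline scaling maps the range endpoints and preserves overshoot", {
  baselines <- do.call(rbind, lapply(
    list(
      c("baseline_all", 0.2), c("baseline_hvg", 0.4),
      c("baseline_random", 0.5), c("baseline_stable", 0.9)
    ),
    function(x) scoreRow("d1", x[1], "m", "batch", as.numeric(x[2]))
  ))
  raw <- rbind(
    scoreRow("d1", "max_hit", "m", "batch", 0.9),
    scoreRow("d1", "min_hit", "m", "batch", 0.2),
    scoreRow("d1", "below", "m", "batch", 0.05),
    scoreRow("d1", "above", "m", "batch", 0.97)
  )
  scaled <- scaleScores(raw, baselines)
  expect_equal(scaled$value[scaled$method == "max_hit"], 1)
  expect_equal(scaled$value[scaled$method == "min_hit"], 0)
  expect_equal(scaled$value[scaled$method == "below"],
    (0.05 - 0.2) / 0.7,
    tolerance = 1e-12
  )
  expect_gt(scaled$value[scaled$method == "above"], 1)
  expect_equal(scaled$raw_value, raw$value)
  # degenerate baseline range: missing with a warning
  flat <- do.call(rbind, lapply(c("b1", "b2"), function(m) {
    scoreRow("d1", m, "m", "batch", 0.5)
  }))
  expect_warning(s2 <- scaleScores(raw[1, ], flat), "degenerate")
  expect_true(is.na(s2$value))
})

test_that("scaling is affine-equivariant", {
  set.seed(40)
  base_vals <- runif(4)
  baselines <- do.call(rbind, lapply(1:4, function(i) {
    scoreRow("d", paste0("b", i), "m", "bio", base_vals[i])
  }))
  raw <- scoreRow("d", "x", "m", "bio", 0.42)
  s1 <- scaleScores(raw, baselines)
  shift <- 0.17
  baselines2 <- baselines
  baselines2$value <- baselines2$value + shift
  raw2 <- raw
  raw2$value <- raw2$value + shift
  s2 <- scaleScores(raw2, baselines2)
  expect_equal(s1$value, s2$value, tolerance = 1e-12)
})

test_that("aggregation implements the stated weighted mean", {
  mk <- function(vals) {
    do.call(rbind, Map(
      function(cat, v) scoreRow("d", "m", paste0("met_", cat), cat, v),
      metricCategories <- c("batch", "bio", "mapping", "classification", "unseen"),
      vals
    ))
  }
  s <- aggregateScores(mk(c(1, 1, 1, 1, 1)))
  expect_equal(s$overall, 1)
  s2 <- aggregateScores(mk(c(1, 0, 0, 0, 0)))
  expect_equal(s2$overall, 0.25)
  s3 <- aggregateScores(mk(c(0.8, 0.6, 0.9, 0.3, 0.6)))
  expect_equal(s3$overall, 0.25 * 0.8 + 0.25 * 0.6 + (0.9 + 0.3 + 0.6) / 6,
    tolerance = 1e-12
  )
  # order of metrics within a category does not matter
  tab <- rbind(
    mk(c(0.8, 0.6, 0.9, 0.3, 0.6)),
    scoreRow("d", "m", "met_b2", "batch", 0.4)
  )
  s4a <- aggregateScores(tab)
  s4b <- aggregateScores(tab[rev(seq_len(nrow(tab))), ])
  expect_equal(s4a$overall, s4b$overall, tolerance = 1e-12)
  expect_equal(s4a$int_batch, 0.6, tolerance = 1e-12)
  # optional metrics never enter category means by default
  tab_opt <- rbind(
    mk(c(0.5, 0.5, 0.5, 0.5, 0.5)),
    scoreRow("d", "m", "knn_correlation", "mapping", 100)
  )
  expect_equal(aggregateScores(tab_opt)$mapping, 0.5)
  # a fully missing category is an error
  expect_error(
    aggregateScores(mk(c(1, 1, 1, 1, 1))[-5, ]),
    "category without"
  )
})

test_that("ranking handles ties, missing cells and monotone transforms", {
  sm <- data.frame(
    dataset = rep(c("d1", "d2"), each = 3),
    method = rep(c("m1", "m2", "m3"), 2),
    int_batch = 1, int_bio = 1, mapping = 1, classification = 1, unseen = 1,
    overall = c(0.9, 0.5, 0.1, 0.8, 0.8, 0.2)
  )
  rk <- rankMethods(sm, levels = "overall")
  d1 <- rk$perDataset[rk$perDataset$dataset == "d1", ]
  expect_equal(d1$rank[order(d1$method)], c(1, 2, 3))
  d2 <- rk$perDataset[rk$perDataset$dataset == "d2", ]
  expect_equal(d2$rank[order(d2$method)], c(1.5, 1.5, 3))
  cross <- rk$crossDataset
  expect_equal(
    cross$mean_rank[cross$method == "m1"],
    mean(c(1, 1.5))
  )
  # brute-force sort oracle on random scores
  set.seed(41)
  sm2 <- sm
  sm2$overall <- runif(6)
  rk2 <- rankMethods(sm2, levels = "overall")
  for (ds in c("d1", "d2")) {
    sub <- sm2[sm2$dataset == ds, ]
    oracle <- rank(-sub$overall)
    got <- rk2$perDataset[rk2$perDataset$dataset == ds, ]
    expect_equal(got$rank[match(sub$method, got$method)], oracle)
  }
  # invariance under a strictly monotone transform
  sm3 <- sm2
  sm3$overall <- exp(3 * sm3$overall)
  rk3 <- rankMethods(sm3, levels = "overall")
  expect_equal(rk3$perDataset$rank, rk2$perDataset$rank)
})

test_that("standardisation matches the direct formula and degenerate rule", {
  df <- data.frame(
    dataset = "d", method = "m", value = c(1, 2, 3)
  )
  z <- standardizeScores(df)$z
  expect_equal(z, c(-1, 0, 1))
  df2 <- data.frame(dataset = "d", method = "m", value = rep(0.4, 5))
  expect_equal(standardizeScores(df2)$z, rep(0, 5))
  set.seed(42)
  df3 <- data.frame(
    dataset = rep(c("a", "b"), each = 10),
    method = "m", value = rnorm(20)
  )
  out <- standardizeScores(df3)
  for (g in c("a", "b")) {
    v <- df3$value[df3$dataset == g]
    expect_equal(
      out$z[out$dataset == g],
      (v - mean(v)) / sd(v),
      tolerance = 1e-12
    )
  }
})

test_that("metric profiling surfaces range, size correlation and redundancy", {
  set.seed(43)
  sizes <- c(100, 500, 1000, 2000)
  mkrow <- function(metric, value, n, type, seed = 0) {
    data.frame(
      metric = metric, dataset = "d", value = value,
      n_features = n, set_type = type, set_seed = seed
    )
  }
  tab <- rbind(
    # metric tracking feature count linearly (ordered sets)
    do.call(rbind, lapply(sizes, function(n) {
      mkrow("linear", n / 2000, n, "ordered")
    })),
    # constant metric: zero observed range on random sets
    do.call(rbind, lapply(1:6, function(s) {
      mkrow("flat", 0.5, 500, "random", s)
    })),
    do.call(rbind, lapply(1:6, function(s) {
      mkrow("varying", c(0.1, 0.9, 0.4, 0.6, 0.2, 0.8)[s], 500, "random", s)
    }))
  )
  prof <- profileMetrics(tab)
  per <- prof$perMetric
  expect_equal(per$observed_range[per$metric == "flat"], 0)
  expect_equal(per$observed_range[per$metric == "varying"], 0.8)
  expect_equal(per$cor_n_features[per$metric == "linear"], 1, tolerance = 1e-12)
  # inter-metric correlations against a direct Pearson oracle
  wide <- matrix(runif(5 * 20), 20, 5,
    dimnames = list(NULL, paste0("M", 1:5))
  )
  long <- do.call(rbind, lapply(1:5, function(j) {
    data.frame(
      metric = paste0("M", j), dataset = "d",
      value = wide[, j], n_features = 500, set_type = "random",
      set_seed = 1:20
    )
  }))
  prof2 <- profileMetrics(long)
  expect_equal(
    prof2$interMetric[paste0("M", 1:5), paste0("M", 1:5)],
    cor(wide),
    tolerance = 1e-12
  )
})
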