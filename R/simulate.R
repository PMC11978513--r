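# Splat-style Poisson-gamma count simulator with per-label differential
# expression, multiplicative batch effects, label-specific extra noise factors
# applied before count sampling, a two-branch trajectory, and a
# reference/query split with designated unseen (query-only) populations.

#' Simulation configuration for the count-level benchmark generator
#'
#' @param nFeatures number of simulated features.
#' @param labelSpec data frame with columns \code{name}, \code{n_cells}
#'   (cells per batch at factor 1), \code{de_prob}, \code{de_scale} and
#'   optionally \code{noise_sd} (per-label extra noise scale).
#' @param batchSpec data frame with columns \code{name}, \code{depth_factor},
#'   \code{n_cells_factor}.
#' @param queryBatches batches forming the query.
#' @param unseenLabels labels generated only in query batches.
#' @param trajectorySpec optional list with elements \code{progenitor}
#'   (label name), \code{branches} (list of character vectors, labels ordered
#'   along each branch) and \code{n_steps} (interpolation steps per branch).
#' @param labelNoiseSd default per-label extra noise sd where
#'   \code{labelSpec$noise_sd} is absent.
#' @param meanShape,meanRate gamma parameters of base gene means.
#' @param deLoc location of log-normal differential expression factors.
#' @param batchLoc,batchSd log-normal multiplicative batch effect parameters
#'   (set \code{batchSd = 0} and \code{batchLoc = 0} to disable).
#' @param libLoc,libSd log-normal library size parameters (before the batch
#'   depth factor).
#' @param bcv biological coefficient of variation of the Poisson-gamma
#'   (negative binomial) count noise.
#' @param seed integer seed; the generator is a pure function of the config.
#' @return a \code{SimConfig} list.
#' @export
simConfig <- function(nFeatures = 1000,
                      labelSpec = NULL,
                      batchSpec = NULL,
                      queryBatches = NULL,
                      unseenLabels = c("Rare", "Perturbed", "Intermediate"),
                      trajectorySpec = list(
                        progenitor = "Progenitor",
                        branches = list(
                          c("Intermediate", "Terminal1"),
                          "Terminal2"
                        ),
                        n_steps = 10
                      ),
                      labelNoiseSd = 0.2,
                      meanShape = 0.6, meanRate = 0.3,
                      deLoc = 0.1,
                      batchLoc = 0.1, batchSd = 0.1,
                      libLoc = log(2500), libSd = 0.2,
                      bcv = 0.2,
                      seed = 1L) {
  if (is.null(labelSpec)) {
    labelSpec <- data.frame(
      name = c(
        "Progenitor", "Intermediate", "Terminal1", "Terminal2",
        "TypeA", "TypeB", "TypeC", "TypeD", "Rare", "Perturbed"
      ),
      n_cells = c(40, 30, 40, 40, 60, 50, 40, 30, 15, 25),
      de_prob = c(0.1, 0.1, 0.1, 0.1, 0.2, 0.15, 0.1, 0.05, 0.3, 0.1),
      de_scale = c(0.4, 0.4, 0.4, 0.4, 0.5, 0.4, 0.4, 0.3, 0.8, 0.3)
    )
  }
  if (is.null(batchSpec)) {
    # three technologies, two batches each: medium cells at medium depth,
    # few cells at high depth, many cells at low depth (the query)
    batchSpec <- data.frame(
      name = paste0("Batch", 1:6),
      depth_factor = c(1, 1, 2, 2, 0.3, 0.3),
      n_cells_factor = c(1, 1, 0.5, 0.5, 1.5, 1.5)
    )
  }
  if (is.null(queryBatches)) queryBatches <- c("Batch5", "Batch6")
  if (is.null(labelSpec$noise_sd)) labelSpec$noise_sd <- labelNoiseSd
  cfg <- list(
    nFeatures = nFeatures, labelSpec = labelSpec, batchSpec = batchSpec,
    queryBatches = as.character(queryBatches),
    unseenLabels = as.character(unseenLabels),
    trajectorySpec = trajectorySpec,
    meanShape = meanShape, meanRate = meanRate, deLoc = deLoc,
    batchLoc = batchLoc, batchSd = batchSd,
    libLoc = libLoc, libSd = libSd, bcv = bcv, seed = as.integer(seed)
  )
  class(cfg) <- c("SimConfig", "list")
  validateSimConfig(cfg)
  cfg
}

validateSimConfig <- function(cfg) {
  assertThat(nrow(cfg$batchSpec) >= 2, "at least 2 batches required")
  assertThat(nrow(cfg$labelSpec) >= 2, "at least 2 labels required")
  assertThat(
    all(cfg$unseenLabels %in% cfg$labelSpec$name),
    "unseen labels must be a subset of label names"
  )
  assertThat(all(cfg$batchSpec$depth_factor > 0), "depth factors must be > 0")
  assertThat(
    all(cfg$queryBatches %in% cfg$batchSpec$name),
    "query batches must appear in the batch spec"
  )
  assertThat(
    all(cfg$labelSpec$n_cells > 0),
    "every label in labelSpec needs at least one cell"
  )
  invisible(cfg)
}

trajectoryLabels <- function(cfg) {
  ts <- cfg$trajectorySpec
  if (is.null(ts)) character() else unique(unlist(ts$branches))
}

#' Simulate a reference/query benchmark dataset at the count level
#'
#' Gamma-distributed base gene means; per-label log-normal differential
#' expression factors applied with probability \code{de_prob}; log-normal
#' multiplicative batch effects; log-normal library sizes scaled by each
#' batch's depth factor; per-cell per-gene label-specific extra noise factors
#' (log-normal, unit mean) applied before count sampling; Poisson-gamma
#' (negative binomial) counts. Trajectory labels are generated by
#' interpolating progenitor and terminal expected expression over
#' \code{n_steps}. Unseen labels are only generated in query batches.
#' Ground truth (differential expression flags, base means, trajectory step)
#' is stored in the provenance.
#'
#' @param cfg a [simConfig()] object.
#' @return A [SplitDataset-class]; deterministic given \code{cfg$seed}.
#' @export
simulateCounts <- function(cfg) {
  validateSimConfig(cfg)
  withSeed(cfg$seed, {
    G <- cfg$nFeatures
    ls_ <- cfg$labelSpec
    bs <- cfg$batchSpec
    traj_labels <- trajectoryLabels(cfg)
    prog <- if (is.null(cfg$trajectorySpec)) NULL else cfg$trajectorySpec$progenitor

    base_means <- rgamma(G, shape = cfg$meanShape, rate = cfg$meanRate)
    base_means <- pmax(base_means, 1e-8)

    # per-label DE factor vectors (interpolated labels get none of their own)
    de_factors <- matrix(1, G, nrow(ls_), dimnames = list(NULL, ls_$name))
    de_flags <- matrix(FALSE, G, nrow(ls_), dimnames = list(NULL, ls_$name))
    for (i in seq_len(nrow(ls_))) {
      nm <- ls_$name[i]
      if (nm %in% traj_labels && !identical(nm, prog)) next
      is_de <- runif(G) < ls_$de_prob[i]
      f <- exp(rnorm(G, cfg$deLoc, ls_$de_scale[i]))
      down <- runif(G) < 0.5
      f[down] <- 1 / f[down]
      fac <- rep(1, G)
      fac[is_de] <- f[is_de]
      de_factors[, nm] <- fac
      de_flags[, nm] <- is_de
    }
    label_means <- base_means * de_factors

    # endpoint profile of each branch = DE profile of its terminal label;
    # non-terminal branch labels get interpolated means per cell below
    branch_of <- list()
    if (!is.null(cfg$trajectorySpec)) {
      for (b in seq_along(cfg$trajectorySpec$branches)) {
        path <- cfg$trajectorySpec$branches[[b]]
        for (j in seq_along(path)) {
          branch_of[[path[j]]] <- list(
            branch = b, segment = j, n_segments = length(path),
            terminal = path[length(path)]
          )
        }
      }
    }

    batch_factors <- matrix(1, G, nrow(bs), dimnames = list(NULL, bs$name))
    if (cfg$batchSd > 0 || cfg$batchLoc != 0) {
      for (i in seq_len(nrow(bs))) {
        f <- exp(rnorm(G, cfg$batchLoc, cfg$batchSd))
        down <- runif(G) < 0.5
        f[down] <- 1 / f[down]
        batch_factors[, i] <- f
      }
    }

    cell_batch <- character()
    cell_label <- character()
    cell_t <- numeric()
    mean_list <- list()
    n_steps <- if (is.null(cfg$trajectorySpec)) 1L else cfg$trajectorySpec$n_steps
    for (bi in seq_len(nrow(bs))) {
      bname <- bs$name[bi]
      is_query_batch <- bname %in% cfg$queryBatches
      for (li in seq_len(nrow(ls_))) {
        lname <- ls_$name[li]
        if (lname %in% cfg$unseenLabels && !is_query_batch) next
        n <- max(1L, as.integer(round(ls_$n_cells[li] * bs$n_cells_factor[bi])))
        if (lname %in% names(branch_of) && !identical(lname, prog)) {
          info <- branch_of[[lname]]
          lo <- (info$segment - 1) / info$n_segments
          hi <- info$segment / info$n_segments
          steps <- seq(lo, hi, length.out = n_steps + 1L)[-1L]
          tvals <- steps[1L + (seq_len(n) - 1L) %% n_steps]
          mu <- outer(base_means * de_factors[, prog], 1 - tvals) +
            outer(base_means * de_factors[, info$terminal], tvals)
        } else {
          tvals <- rep(NA_real_, n)
          mu <- matrix(label_means[, lname], G, n)
        }
        mu <- mu * batch_factors[, bname]
        mean_list[[length(mean_list) + 1L]] <- mu
        cell_batch <- c(cell_batch, rep(bname, n))
        cell_label <- c(cell_label, rep(lname, n))
        cell_t <- c(cell_t, tvals)
      }
    }
    mu_all <- do.call(cbind, mean_list) # genes x cells
    n_cells <- ncol(mu_all)

    # label-specific extra noise factors, unit-mean log-normal, pre-count
    noise_sd <- ls_$noise_sd[match(cell_label, ls_$name)]
    for (ci in which(noise_sd > 0)) {
      s <- noise_sd[ci]
      mu_all[, ci] <- mu_all[, ci] * exp(rnorm(G, -s^2 / 2, s))
    }

    depth <- bs$depth_factor[match(cell_batch, bs$name)]
    libsize <- depth * rlnorm(n_cells, cfg$libLoc, cfg$libSd)
    lambda <- sweep(mu_all, 2, libsize / colSums(mu_all), `*`)

    if (cfg$bcv > 0) {
      shape <- 1 / cfg$bcv^2
      lambda <- matrix(
        rgamma(length(lambda), shape = shape, rate = shape / pmax(lambda, 1e-12)),
        G, n_cells
      )
    }
    counts <- matrix(rpois(length(lambda), lambda), G, n_cells)

    cell_ids <- sprintf("Cell%05d", seq_len(n_cells))
    gene_ids <- sprintf("Gene%04d", seq_len(G))
    m <- t(counts)
    dimnames(m) <- list(cell_ids, gene_ids)
    is_query <- cell_batch %in% cfg$queryBatches
    ref <- CellMatrix(
      m[!is_query, , drop = FALSE],
      cell_batch[!is_query], cell_label[!is_query]
    )
    qry <- CellMatrix(
      m[is_query, , drop = FALSE],
      cell_batch[is_query], cell_label[is_query]
    )
    SplitDataset(ref, qry,
      unseenLabels = cfg$unseenLabels,
      provenance = list(
        generator = "simulateCounts", seed = cfg$seed,
        ground_truth = list(
          base_means = setNames(base_means, gene_ids),
          de_flags = `rownames<-`(de_flags, gene_ids),
          de_factors = `rownames<-`(de_factors, gene_ids),
          trajectory_step = setNames(cell_t, cell_ids),
          library_size = setNames(libsize, cell_ids)
        )
      )
    )
  })
}

#' Embedding-level benchmark generator configuration
#'
#' Fast fixture for metric tests: cells are drawn from Gaussian clusters
#' around per-label centers, each batch is offset by a Gaussian shift, query
#' batches by an additional shift, and unseen labels are placed either far
#' from all reference centers or merged onto an existing one.
#'
#' @param d latent dimension (>= 2).
#' @param labels,batches label and batch names.
#' @param queryBatches batches forming the query.
#' @param unseenLabels query-only labels.
#' @param centers "auto" (random placement with minimum separation
#'   \code{minSep}) or a labels x d matrix.
#' @param minSep minimum center separation for auto placement
#'   (default \code{10 * clusterSd}).
#' @param batchShiftSd sd of the per-batch offset vector.
#' @param queryShiftSd sd of the additional query offset.
#' @param unseenPlacement "far" (>= 6 * clusterSd from every center) or
#'   "merged" (on an existing center).
#' @param clusterSd within-cluster standard deviation (> 0).
#' @param nPerGroup cells per (label, batch) combination.
#' @param seed integer seed.
#' @return an \code{EmbConfig} list.
#' @export
embConfig <- function(d = 10, labels = c("A", "B", "C"),
                      batches = c("b1", "b2", "q1"),
                      queryBatches = "q1",
                      unseenLabels = character(),
                      centers = "auto", minSep = NULL,
                      batchShiftSd = 0.5, queryShiftSd = 0.5,
                      unseenPlacement = c("far", "merged"),
                      clusterSd = 1, nPerGroup = 50, seed = 1L) {
  unseenPlacement <- match.arg(unseenPlacement)
  assertThat(d >= 2, "latent dimension must be >= 2")
  assertThat(clusterSd > 0, "clusterSd must be > 0")
  assertThat(
    all(queryBatches %in% batches),
    "query batches must be among batches"
  )
  assertThat(
    all(unseenLabels %in% labels),
    "unseen labels must be among labels"
  )
  if (is.null(minSep)) minSep <- 10 * clusterSd
  cfg <- list(
    d = d, labels = labels, batches = batches,
    queryBatches = queryBatches, unseenLabels = unseenLabels,
    centers = centers, minSep = minSep,
    batchShiftSd = batchShiftSd, queryShiftSd = queryShiftSd,
    unseenPlacement = unseenPlacement, clusterSd = clusterSd,
    nPerGroup = nPerGroup, seed = as.integer(seed)
  )
  class(cfg) <- c("EmbConfig", "list")
  cfg
}

autoCenters <- function(k, d, minSep) {
  centers <- matrix(0, k, d)
  for (i in seq_len(k)) {
    for (attempt in 1:500) {
      cand <- rnorm(d, 0, minSep)
      if (i == 1 || min(sqrt(rowSums(sweep(
        centers[seq_len(i - 1), , drop = FALSE], 2, cand
      )^2))) >= minSep) {
        centers[i, ] <- cand
        break
      }
      if (attempt == 500) stop("could not place separated centers")
    }
  }
  centers
}

#' Simulate a joint embedding with known structure
#'
#' @param cfg an [embConfig()] object.
#' @return list with \code{embedding} ([JointEmbedding-class]),
#'   \code{refLabels}, \code{refBatches}, \code{queryLabels},
#'   \code{queryBatches} (factors) and \code{centers}.
#' @export
simulateEmbedding <- function(cfg) {
  withSeed(cfg$seed, {
    seen <- setdiff(cfg$labels, cfg$unseenLabels)
    if (identical(cfg$centers, "auto")) {
      centers <- autoCenters(length(seen), cfg$d, cfg$minSep)
      rownames(centers) <- seen
    } else {
      centers <- as.matrix(cfg$centers)[seen, , drop = FALSE]
    }
    all_centers <- centers
    for (ul in cfg$unseenLabels) {
      if (cfg$unseenPlacement == "merged") {
        uc <- centers[1, ]
      } else {
        centroid <- colMeans(centers)
        dirv <- rnorm(cfg$d)
        dirv <- dirv / sqrt(sum(dirv^2))
        radius <- max(sqrt(rowSums(sweep(centers, 2, centroid)^2)))
        uc <- centroid + dirv * (radius + cfg$minSep + 6 * cfg$clusterSd)
        # guarantee the separation bound against every center
        while (min(sqrt(rowSums(sweep(all_centers, 2, uc)^2))) <
          6 * cfg$clusterSd) {
          uc <- uc + dirv * cfg$clusterSd
        }
      }
      all_centers <- rbind(all_centers, uc)
      rownames(all_centers)[nrow(all_centers)] <- ul
    }
    batch_shift <- matrix(
      rnorm(length(cfg$batches) * cfg$d, 0, cfg$batchShiftSd),
      length(cfg$batches), cfg$d,
      dimnames = list(cfg$batches, NULL)
    )
    query_shift <- rnorm(cfg$d, 0, cfg$queryShiftSd)

    rows <- list()
    lab <- character()
    bat <- character()
    for (b in cfg$batches) {
      is_q <- b %in% cfg$queryBatches
      for (l in cfg$labels) {
        if (l %in% cfg$unseenLabels && !is_q) next
        n <- cfg$nPerGroup
        x <- matrix(rnorm(n * cfg$d, 0, cfg$clusterSd), n, cfg$d)
        x <- sweep(x, 2, all_centers[l, ] + batch_shift[b, ], `+`)
        if (is_q) x <- sweep(x, 2, query_shift, `+`)
        rows[[length(rows) + 1L]] <- x
        lab <- c(lab, rep(l, n))
        bat <- c(bat, rep(b, n))
      }
    }
    coords <- do.call(rbind, rows)
    rownames(coords) <- sprintf("ecell%05d", seq_len(nrow(coords)))
    is_q <- bat %in% cfg$queryBatches
    list(
      embedding = JointEmbedding(
        coords[!is_q, , drop = FALSE],
        coords[is_q, , drop = FALSE]
      ),
      refLabels = factor(lab[!is_q]), refBatches = factor(bat[!is_q]),
      queryLabels = factor(lab[is_q]), queryBatches = factor(bat[is_q]),
      centers = all_centers
    )
  })
}

#' Fixture integrator: PCA plus tunable batch mean removal
#'
#' Stands in for a real integration model so that metric behaviour can be
#' tested against a known amount of residual batch effect. Counts are
#' normalised (counts per 10k, log1p), a PCA is fitted on the reference and
#' the query projected into it, and each cell is shifted by
#' \code{-removal * (batch mean - global mean)} in PC space. \code{removal =
#' 0} returns the uncorrected PCA; \code{removal = 1} fully centers batch
#' means. The uncorrected PCA is kept as the pre-integration embedding.
#'
#' @param ds a prepared [SplitDataset-class].
#' @param nPcs number of principal components.
#' @param removal batch effect removal strength in \[0, 1\].
#' @param features optional feature subset (ids or indices) to use.
#' @param seed unused randomness guard (PCA is deterministic); kept for
#'   interface uniformity.
#' @return A [JointEmbedding-class] with pre-integration coordinates.
#' @export
fixtureIntegrate <- function(ds, nPcs = 10, removal = 1, features = NULL,
                             seed = NULL) {
  assertThat(removal >= 0 && removal <= 1, "removal must be in [0, 1]")
  ref <- reference(ds)
  qry <- query(ds)
  if (!is.null(features)) {
    ref <- ref[, features]
    qry <- qry[, features]
  }
  nPcs <- min(nPcs, nCells(ref) - 1L, nFeatures(ref))
  xr <- denseCounts(logNormalize(counts(ref)))
  xq <- denseCounts(logNormalize(counts(qry)))
  ctr <- colMeans(xr)
  pca <- prcomp(xr, rank. = nPcs, center = TRUE, scale. = FALSE)
  if (all(pca$sdev[seq_len(nPcs)] < 1e-12)) {
    stop("degenerate PCA: no variance in the reference", call. = FALSE)
  }
  rot <- pca$rotation
  # canonical sign: largest-magnitude loading positive
  for (j in seq_len(ncol(rot))) {
    peak <- which.max(abs(rot[, j]))
    if (rot[peak, j] < 0) rot[, j] <- -rot[, j]
  }
  sc_ref <- sweep(xr, 2, ctr) %*% rot
  sc_qry <- sweep(xq, 2, ctr) %*% rot
  pre <- rbind(sc_ref, sc_qry)
  batches <- c(as.character(cellBatch(ref)), as.character(cellBatch(qry)))
  global_mean <- colMeans(pre)
  corrected <- pre
  for (b in unique(batches)) {
    idx <- which(batches == b)
    shift <- colMeans(pre[idx, , drop = FALSE]) - global_mean
    corrected[idx, ] <- sweep(pre[idx, , drop = FALSE], 2, removal * shift)
  }
  n_ref <- nCells(ref)
  JointEmbedding(
    corrected[seq_len(n_ref), , drop = FALSE],
    corrected[-seq_len(n_ref), , drop = FALSE],
    preIntegration = pre
  )
}
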