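#' Compute the selected benchmark metric panel
#'
#' Runs the full selected metric set on one integrated embedding: three
#' Integration (Batch) metrics (batch PCR, CMS, iLISI), six Integration (Bio)
#' metrics (isolated label ASW and F1, bNMI, cLISI, ldfDiff, graph
#' connectivity), four mapping metrics (cell distance, label distance, mLISI,
#' qLISI), three classification metrics (F1 macro / micro / rarity) and three
#' unseen population metrics (Milo, unseen cell distance, unseen label
#' distance). With \code{includeOptional = TRUE} the kNN correlation and
#' unseen uncertainty metrics (and the remaining classification scores) are
#' appended; they stay excluded from category means downstream.
#'
#' @param ds a [SplitDataset-class].
#' @param emb a [JointEmbedding-class] for \code{ds}.
#' @param tr a [TransferResult-class] for the query cells (from
#'   [transferLabels()]); computed on the fly when NULL.
#' @param cfg a [metricConfig()].
#' @param dataset,method identifiers written into the score table.
#' @param includeOptional also compute the optional metrics.
#' @return a score table data frame (dataset, method, metric, category,
#'   value).
#' @export
computeMetrics <- function(ds, emb, tr = NULL, cfg = metricConfig(),
                           dataset = "dataset", method = "method",
                           includeOptional = FALSE) {
  ref <- reference(ds)
  qry <- query(ds)
  ref_labels <- cellLabel(ref)
  ref_batches <- cellBatch(ref)
  q_labels <- cellLabel(qry)
  q_batches <- cellBatch(qry)
  unseen <- unseenLabels(ds)
  if (is.null(tr)) tr <- transferLabels(emb, ref_labels)
  rc <- refCoords(emb)
  qc <- queryCoords(emb)
  all_coords <- rbind(rc, qc)
  all_batch <- factor(c(as.character(ref_batches), as.character(q_batches)))
  all_labels <- c(as.character(ref_labels), as.character(q_labels))
  origin <- factor(rep(c("reference", "query"), c(nrow(rc), nrow(qc))))

  scores <- list()
  add <- function(ms) scores[[length(scores) + 1L]] <<- ms

  # Integration (Batch)
  add(batchPCR(emb, ref_batches, cfg = cfg))
  add(cmsScore(rc, ref_batches, cfg = cfg))
  add(lisiScore(rc, ref_batches, "ilisi", cfg))

  # Integration (Bio); one Leiden resolution sweep shared by bNMI and the
  # isolated label F1
  sweep <- clusterSweep(rc, function(cl) bnmi(cl, ref_labels, ref_batches), cfg)
  iso <- isolatedLabelScores(rc, ref_labels, ref_batches, cfg, sweep = sweep)
  add(iso$asw)
  add(iso$f1)
  add(bnmiScore(rc, ref_labels, ref_batches, cfg, sweep = sweep))
  add(lisiScore(rc, ref_labels, "clisi", cfg))
  if (!is.null(preIntegration(emb))) {
    add(ldfDiff(emb, all_batch, cfg))
  }
  add(graphConnectivity(rc, ref_labels, cfg))

  # Mapping quality
  add(cellDistance(emb, ref_labels, q_labels, unseen, cfg))
  add(labelDistance(emb, ref_labels, q_labels, unseen, cfg))
  add(lisiScore(all_coords, origin, "mlisi", cfg))
  if (nlevels(droplevels(q_batches)) >= 2) {
    add(lisiScore(qc, q_batches, "qlisi", cfg))
  }

  # Classification
  cls <- classificationScores(tr, q_labels, unseen)
  add(cls$f1_macro)
  add(cls$f1_micro)
  add(cls$f1_rarity)

  # Unseen populations
  if (length(unseen)) {
    add(miloScore(emb, all_batch, origin == "query", all_labels, unseen, cfg,
      cellIds = c(cellIds(ref), cellIds(qry))
    ))
    add(unseenCellDistance(emb, ref_labels, q_labels, unseen, cfg))
    add(unseenLabelDistance(emb, ref_labels, q_labels, unseen, cfg))
  }

  if (includeOptional) {
    add(knnCorrelation(ds, emb, cfg = cfg))
    for (nm in c(
      "accuracy", "jaccard_micro", "jaccard_macro",
      "jaccard_rarity", "mcc01", "auprc_macro"
    )) {
      add(cls[[nm]])
    }
    if (length(unseen)) {
      add(unseenUncertainty(tr, as.character(q_labels) %in% unseen))
    }
  }

  data.frame(
    dataset = dataset, method = method,
    metric = vapply(scores, `[[`, character(1), "name"),
    category = vapply(scores, `[[`, character(1), "category"),
    value = vapply(scores, `[[`, numeric(1), "value"),
    stringsAsFactors = FALSE
  )
}
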