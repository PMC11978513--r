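#' Preprocess and split an annotated count matrix into reference and query
#'
#' Applies the benchmark's preprocessing procedure in a fixed order:
#' cell quality filtering (minimum total counts and expressed features),
#' reference/query split by batch, removal of small labels (per half,
#' independently), removal of unseen labels from the reference, and removal of
#' features not expressed in any reference cell (from both halves). Every
#' removal is logged in the provenance slot.
#'
#' @param raw a [CellMatrix-class] with batch and label annotations.
#' @param queryBatches nonempty character vector of batches forming the query.
#' @param unseenLabels labels treated as unseen populations: removed from the
#'   reference, kept in the query. Each must still be present in the query
#'   after filtering.
#' @param minCounts cells with fewer total counts are removed (default 100).
#' @param minFeatures cells expressing fewer features are removed (default 100).
#' @param minLabelCells labels with fewer cells in a half are removed from that
#'   half (default 20).
#' @return A [SplitDataset-class].
#' @examples
#' ds <- simulateCounts(simConfig(seed = 1))
#' ds
#' @export
prepareSplit <- function(raw, queryBatches, unseenLabels = character(),
                         minCounts = 100, minFeatures = 100,
                         minLabelCells = 20) {
  assertThat(methods::is(raw, "CellMatrix"), "raw must be a CellMatrix")
  queryBatches <- as.character(queryBatches)
  unseenLabels <- as.character(unseenLabels)
  assertThat(length(queryBatches) > 0, "queryBatches must be nonempty")
  missing_b <- setdiff(queryBatches, levels(cellBatch(raw)))
  assertThat(
    length(missing_b) == 0,
    "query batches not present in data: ", paste(missing_b, collapse = ", ")
  )
  prov <- list(
    cells_in = nCells(raw), features_in = nFeatures(raw),
    params = list(
      minCounts = minCounts, minFeatures = minFeatures,
      minLabelCells = minLabelCells
    )
  )
  cts <- counts(raw)
  batches_in <- levels(droplevels(cellBatch(raw)))

  # 1. cell QC
  totals <- Matrix::rowSums(cts)
  n_expr <- Matrix::rowSums(cts > 0)
  keep <- totals >= minCounts & n_expr >= minFeatures
  prov$cells_removed_qc <- sum(!keep)
  raw <- raw[which(keep), ]
  lost_batches <- setdiff(batches_in, as.character(unique(cellBatch(raw))))
  if (length(lost_batches)) {
    warning(
      "all cells of batch(es) removed by QC: ",
      paste(lost_batches, collapse = ", ")
    )
  }

  # 2. reference/query split by batch
  is_query <- as.character(cellBatch(raw)) %in% queryBatches
  ref <- raw[which(!is_query), ]
  qry <- raw[which(is_query), ]
  assertThat(nCells(ref) > 0, "no reference cells remain after split")
  assertThat(nCells(qry) > 0, "no query cells remain after split")
  prov$cells_reference <- nCells(ref)
  prov$cells_query <- nCells(qry)

  # 3. label size filter, applied to each half independently
  dropSmallLabels <- function(cm) {
    tab <- table(cellLabel(cm))
    small <- names(tab)[tab < minLabelCells]
    keep <- !(as.character(cellLabel(cm)) %in% small)
    list(cm = cm[which(keep), ], removed = sum(!keep), labels = small)
  }
  r <- dropSmallLabels(ref)
  q <- dropSmallLabels(qry)
  prov$cells_removed_small_labels <- list(
    reference = r$removed, query = q$removed,
    labels = union(r$labels, q$labels)
  )
  ref <- r$cm
  qry <- q$cm

  # 4. unseen labels removed from the reference only
  drop_unseen <- as.character(cellLabel(ref)) %in% unseenLabels
  prov$cells_removed_unseen_reference <- sum(drop_unseen)
  ref <- ref[which(!drop_unseen), ]
  missing_u <- setdiff(unseenLabels, as.character(unique(cellLabel(qry))))
  assertThat(
    length(missing_u) == 0,
    "unseen label(s) absent from the query after filtering: ",
    paste(missing_u, collapse = ", ")
  )

  # 5. drop features unexpressed in the reference, from both halves
  expressed <- Matrix::colSums(counts(ref) > 0) > 0
  prov$features_removed_unexpressed <- sum(!expressed)
  ref <- ref[, which(expressed)]
  qry <- qry[, which(expressed)]

  prov$cells_out <- nCells(ref) + nCells(qry)
  prov$features_out <- nFeatures(ref)
  SplitDataset(ref, qry, unseenLabels = unseenLabels, provenance = prov)
}

#' Reassemble the raw CellMatrix underlying a SplitDataset
#'
#' Stacks reference then query cells back into one [CellMatrix-class], e.g.
#' for re-running preprocessing or writing a combined file.
#'
#' @param ds a [SplitDataset-class].
#' @return a [CellMatrix-class].
#' @export
combineHalves <- function(ds) {
  ref <- reference(ds)
  qry <- query(ds)
  CellMatrix(
    rbind(counts(ref), counts(qry)),
    batch = c(as.character(cellBatch(ref)), as.character(cellBatch(qry))),
    label = c(as.character(cellLabel(ref)), as.character(cellLabel(qry)))
  )
}
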