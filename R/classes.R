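setClassUnion("matrixOrSparse", c("matrix", "Matrix"))
setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' CellMatrix: annotated single-cell count matrix
#'
#' Container for a cells x features count matrix with per-cell batch and label
#' annotations. Cells are always rows; all per-cell vectors are row-aligned.
#' Cell and feature identifiers are held as the dimnames of the count matrix
#' and must be unique.
#'
#' @slot counts non-negative count matrix (dense or \pkg{Matrix} sparse),
#'   cells x features, with unique dimnames.
#' @slot batch factor of per-cell batch assignments.
#' @slot label factor of per-cell label (cell type) assignments.
#'
#' @exportClass CellMatrix
setClass("CellMatrix",
  representation(counts = "matrixOrSparse", batch = "factor", label = "factor")
)

setValidity("CellMatrix", function(object) {
  cts <- object@counts
  msgs <- character()
  if (is.null(rownames(cts)) || is.null(colnames(cts))) {
    msgs <- c(msgs, "counts must have cell (row) and feature (column) names")
  } else {
    if (anyDuplicated(rownames(cts))) msgs <- c(msgs, "duplicate cell ids")
    if (anyDuplicated(colnames(cts))) msgs <- c(msgs, "duplicate feature ids")
  }
  if (length(object@batch) != nrow(cts)) {
    msgs <- c(msgs, "batch length must equal number of cells")
  }
  if (length(object@label) != nrow(cts)) {
    msgs <- c(msgs, "label length must equal number of cells")
  }
  vals <- if (inherits(cts, "sparseMatrix")) cts@x else cts
  if (length(vals) && (any(!is.finite(vals)) || any(vals < 0))) {
    msgs <- c(msgs, "counts must be finite and non-negative")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a CellMatrix
#'
#' @param counts cells x features count matrix with dimnames (dense or sparse).
#' @param batch per-cell batch assignment (coerced to factor).
#' @param label per-cell label assignment (coerced to factor).
#' @return A [CellMatrix-class] object.
#' @examples
#' m <- matrix(rpois(20, 2), 4, 5,
#'   dimnames = list(paste0("c", 1:4), paste0("g", 1:5))
#' )
#' cm <- CellMatrix(m, batch = c("a", "a", "b", "b"), label = rep("T", 4))
#' nCells(cm)
#' @export
CellMatrix <- function(counts, batch, label) {
  new("CellMatrix",
    counts = counts,
    batch = factor(batch), label = factor(label)
  )
}

#' SplitDataset: reference/query benchmark dataset
#'
#' Holds the reference and query halves of a benchmark dataset after
#' preprocessing, together with the set of labels designated as unseen
#' populations (present in the query, removed from the reference) and a
#' provenance log of filtering steps.
#'
#' @slot reference [CellMatrix-class] of reference cells.
#' @slot query [CellMatrix-class] of query cells.
#' @slot unseenLabels character vector of unseen population labels.
#' @slot provenance list logging every filter applied and cells/features removed.
#'
#' @exportClass SplitDataset
setClass("SplitDataset",
  representation(
    reference = "CellMatrix", query = "CellMatrix",
    unseenLabels = "character", provenance = "list"
  )
)

setValidity("SplitDataset", function(object) {
  msgs <- character()
  fr <- colnames(object@reference@counts)
  fq <- colnames(object@query@counts)
  if (!identical(fr, fq)) {
    msgs <- c(msgs, "reference and query feature ids must be identical and ordered identically")
  }
  if (any(object@unseenLabels %in% as.character(object@reference@label))) {
    msgs <- c(msgs, "unseen labels must not occur in the reference")
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname SplitDataset-class
#' @param reference,query [CellMatrix-class] halves sharing the same features.
#' @param unseenLabels labels present only in the query.
#' @param provenance preprocessing log.
#' @export
SplitDataset <- function(reference, query, unseenLabels = character(),
                         provenance = list()) {
  new("SplitDataset",
    reference = reference, query = query,
    unseenLabels = as.character(unseenLabels), provenance = provenance
  )
}

#' JointEmbedding: shared latent space for reference and mapped query
#'
#' Coordinates of reference cells and mapped query cells in one integrated
#' low-dimensional space, optionally carrying a pre-integration embedding
#' (for example a PCA of the selected features) used by comparison metrics.
#' Row order matches the cell order of the corresponding
#' [SplitDataset-class] halves.
#'
#' @slot refCoords numeric matrix n_ref x d.
#' @slot queryCoords numeric matrix n_query x d.
#' @slot preIntegration optional numeric matrix (n_ref + n_query) x d0 in a
#'   common unintegrated space, reference rows first; or NULL.
#'
#' @exportClass JointEmbedding
setClass("JointEmbedding",
  representation(
    refCoords = "matrix", queryCoords = "matrix",
    preIntegration = "matrixOrNULL"
  )
)

setValidity("JointEmbedding", function(object) {
  msgs <- character()
  if (ncol(object@refCoords) != ncol(object@queryCoords)) {
    msgs <- c(msgs, "reference and query coordinates must share a dimension")
  }
  if (any(!is.finite(object@refCoords)) || any(!is.finite(object@queryCoords))) {
    msgs <- c(msgs, "coordinates must be finite")
  }
  if (!is.null(object@preIntegration) &&
    nrow(object@preIntegration) != nrow(object@refCoords) + nrow(object@queryCoords)) {
    msgs <- c(msgs, "pre-integration embedding must cover reference then query rows")
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname JointEmbedding-class
#' @param refCoords,queryCoords coordinate matrices with equal column count.
#' @param preIntegration optional stacked (ref then query) unintegrated matrix.
#' @export
JointEmbedding <- function(refCoords, queryCoords, preIntegration = NULL) {
  new("JointEmbedding",
    refCoords = as.matrix(refCoords),
    queryCoords = as.matrix(queryCoords),
    preIntegration = if (is.null(preIntegration)) NULL else as.matrix(preIntegration)
  )
}

#' TransferResult: label transfer predictions
#'
#' Per-query-cell predicted reference label and the full class probability
#' matrix from the label-transfer classifier.
#'
#' @slot predicted character vector of predicted labels.
#' @slot probabilities n_query x L probability matrix; rows sum to 1.
#' @slot classes ordered reference label set (lexicographic).
#'
#' @exportClass TransferResult
setClass("TransferResult",
  representation(
    predicted = "character", probabilities = "matrix",
    classes = "character"
  )
)

setValidity("TransferResult", function(object) {
  msgs <- character()
  if (ncol(object@probabilities) != length(object@classes)) {
    msgs <- c(msgs, "probability columns must match classes")
  }
  if (length(object@predicted) != nrow(object@probabilities)) {
    msgs <- c(msgs, "predicted length must match probability rows")
  }
  if (nrow(object@probabilities) &&
    any(abs(rowSums(object@probabilities) - 1) > 1e-9)) {
    msgs <- c(msgs, "probability rows must sum to 1")
  }
  if (length(msgs)) msgs else TRUE
})

# ---- generics + accessors ---------------------------------------------------

#' @export
setGeneric("counts", function(object, ...) standardGeneric("counts"))
#' @export
setGeneric("cellIds", function(object) standardGeneric("cellIds"))
#' @export
setGeneric("featureIds", function(object) standardGeneric("featureIds"))
#' @export
setGeneric("cellBatch", function(object) standardGeneric("cellBatch"))
#' @export
setGeneric("cellLabel", function(object) standardGeneric("cellLabel"))
#' @export
setGeneric("nCells", function(object) standardGeneric("nCells"))
#' @export
setGeneric("nFeatures", function(object) standardGeneric("nFeatures"))
#' @export
setGeneric("reference", function(object) standardGeneric("reference"))
#' @export
setGeneric("query", function(object) standardGeneric("query"))
#' @export
setGeneric("unseenLabels", function(object) standardGeneric("unseenLabels"))
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @export
setGeneric("refCoords", function(object) standardGeneric("refCoords"))
#' @export
setGeneric("queryCoords", function(object) standardGeneric("queryCoords"))
#' @export
setGeneric("preIntegration", function(object) standardGeneric("preIntegration"))
#' @export
setGeneric("embeddingDim", function(object) standardGeneric("embeddingDim"))
#' @export
setGeneric("predictedLabels", function(object) standardGeneric("predictedLabels"))
#' @export
setGeneric("classProbabilities", function(object) standardGeneric("classProbabilities"))
#' @export
setGeneric("transferClasses", function(object) standardGeneric("transferClasses"))

#' @describeIn CellMatrix-class count matrix (cells x features).
#' @param object a CellMatrix.
#' @param ... unused.
#' @export
setMethod("counts", "CellMatrix", function(object, ...) object@counts)
#' @describeIn CellMatrix-class cell identifiers.
#' @export
setMethod("cellIds", "CellMatrix", function(object) rownames(object@counts))
#' @describeIn CellMatrix-class feature identifiers.
#' @export
setMethod("featureIds", "CellMatrix", function(object) colnames(object@counts))
#' @describeIn CellMatrix-class per-cell batch factor.
#' @export
setMethod("cellBatch", "CellMatrix", function(object) object@batch)
#' @describeIn CellMatrix-class per-cell label factor.
#' @export
setMethod("cellLabel", "CellMatrix", function(object) object@label)
#' @describeIn CellMatrix-class number of cells.
#' @export
setMethod("nCells", "CellMatrix", function(object) nrow(object@counts))
#' @describeIn CellMatrix-class number of features.
#' @export
setMethod("nFeatures", "CellMatrix", function(object) ncol(object@counts))

#' Subset a CellMatrix by cells (i) and/or features (j)
#'
#' @param x a [CellMatrix-class].
#' @param i,j cell and feature indices.
#' @param ... unused.
#' @param drop ignored; dimensions are always kept.
#' @export
setMethod("[", "CellMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@counts))
  if (missing(j)) j <- seq_len(ncol(x@counts))
  if (is.character(i)) i <- match(i, rownames(x@counts))
  CellMatrix(
    x@counts[i, j, drop = FALSE],
    droplevels(x@batch[i]), droplevels(x@label[i])
  )
})

#' @describeIn SplitDataset-class reference half.
#' @param object a SplitDataset.
#' @export
setMethod("reference", "SplitDataset", function(object) object@reference)
#' @describeIn SplitDataset-class query half.
#' @export
setMethod("query", "SplitDataset", function(object) object@query)
#' @describeIn SplitDataset-class unseen population labels.
#' @export
setMethod("unseenLabels", "SplitDataset", function(object) object@unseenLabels)
#' @describeIn SplitDataset-class preprocessing log.
#' @export
setMethod("provenance", "SplitDataset", function(object) object@provenance)

#' @describeIn JointEmbedding-class reference coordinates.
#' @param object a JointEmbedding.
#' @export
setMethod("refCoords", "JointEmbedding", function(object) object@refCoords)
#' @describeIn JointEmbedding-class mapped query coordinates.
#' @export
setMethod("queryCoords", "JointEmbedding", function(object) object@queryCoords)
#' @describeIn JointEmbedding-class pre-integration embedding or NULL.
#' @export
setMethod("preIntegration", "JointEmbedding", function(object) object@preIntegration)
#' @describeIn JointEmbedding-class latent dimension.
#' @export
setMethod("embeddingDim", "JointEmbedding", function(object) ncol(object@refCoords))

#' @describeIn TransferResult-class predicted labels.
#' @param object a TransferResult.
#' @export
setMethod("predictedLabels", "TransferResult", function(object) object@predicted)
#' @describeIn TransferResult-class probability matrix.
#' @export
setMethod("classProbabilities", "TransferResult", function(object) object@probabilities)
#' @describeIn TransferResult-class ordered class labels.
#' @export
setMethod("transferClasses", "TransferResult", function(object) object@classes)

setMethod("show", "CellMatrix", function(object) {
  cat(
    "CellMatrix:", nrow(object@counts), "cells x", ncol(object@counts),
    "features\n  batches:", paste(levels(object@batch), collapse = ", "),
    "\n  labels: ", paste(levels(object@label), collapse = ", "), "\n"
  )
})

setMethod("show", "SplitDataset", function(object) {
  cat(
    "SplitDataset\n  reference:", nCells(object@reference), "cells,",
    nlevels(object@reference@batch), "batches,",
    nlevels(object@reference@label), "labels\n  query:    ",
    nCells(object@query), "cells,", nlevels(object@query@batch), "batches,",
    nlevels(object@query@label), "labels\n  features: ",
    nFeatures(object@reference),
    "\n  unseen:   ", paste(object@unseenLabels, collapse = ", "), "\n"
  )
})

setMethod("show", "JointEmbedding", function(object) {
  cat(
    "JointEmbedding: d =", ncol(object@refCoords), "|",
    nrow(object@refCoords), "reference +", nrow(object@queryCoords),
    "query cells |", if (is.null(object@preIntegration)) {
      "no pre-integration space"
    } else {
      paste0("pre-integration d0 = ", ncol(object@preIntegration))
    }, "\n"
  )
})

setMethod("show", "TransferResult", function(object) {
  cat(
    "TransferResult:", length(object@predicted), "query cells,",
    length(object@classes), "classes\n"
  )
})
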