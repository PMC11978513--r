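#' Transfer reference labels to mapped query cells
#'
#' Fits an L2-regularised multinomial logistic regression on the reference
#' cells' integrated coordinates and ground-truth labels, then predicts a
#' probability for every reference label for each query cell from the fitted
#' softmax. The predicted label is the class with the highest probability
#' (ties broken by class order, which is lexicographic).
#'
#' @param emb a [JointEmbedding-class].
#' @param refLabels per-reference-cell labels, row-aligned with
#'   \code{refCoords(emb)}.
#' @param regularization L2 weight decay of the fit (C-equivalent inverse
#'   strength; the penalty applied is \code{1 / regularization} per squared
#'   coefficient, default 1.0).
#' @param seed seed guarding the solver initialisation (default 1).
#' @return a [TransferResult-class].
#' @export
transferLabels <- function(emb, refLabels, regularization = 1.0, seed = 1L) {
  x <- refCoords(emb)
  assertThat(
    nrow(x) == length(refLabels),
    "refLabels must align with reference coordinates"
  )
  assertThat(all(is.finite(x)), "non-finite reference coordinates")
  classes <- sort(unique(as.character(refLabels)))
  assertThat(length(classes) >= 2, "label transfer needs >= 2 reference labels")
  y <- factor(as.character(refLabels), levels = classes)
  # center on the reference so global coordinate shifts cannot interact with
  # the weight decay penalty (shift invariance by construction)
  ctr <- colMeans(x)
  x <- sweep(x, 2, ctr)
  df <- as.data.frame(x)
  colnames(df) <- paste0("V", seq_len(ncol(df)))
  df$.label <- y
  fit <- withSeed(seed, {
    nnet::multinom(.label ~ ., df,
      decay = 1 / regularization, trace = FALSE,
      maxit = 1000, reltol = 1e-10, MaxNWts = 1e5
    )
  })
  q <- queryCoords(emb)
  assertThat(all(is.finite(q)), "non-finite query coordinates")
  q <- sweep(q, 2, ctr)
  qdf <- as.data.frame(q)
  colnames(qdf) <- paste0("V", seq_len(ncol(qdf)))
  prob <- predict(fit, newdata = qdf, type = "probs")
  if (is.null(dim(prob))) {
    # two-class fits return P(second class) only
    prob <- cbind(1 - prob, prob)
    colnames(prob) <- classes
  }
  prob <- prob[, classes, drop = FALSE]
  prob <- prob / rowSums(prob)
  predicted <- classes[max.col(prob, ties.method = "first")]
  rownames(prob) <- rownames(queryCoords(emb))
  new("TransferResult",
    predicted = predicted, probabilities = prob,
    classes = classes
  )
}
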