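# Classification metrics over the transferred labels: accuracy, averaged F1
# and Jaccard (micro / macro / rarity-weighted), MCC rescaled to [0, 1] and
# macro-averaged area under the precision-recall curve.

# Average precision (area under the precision-recall curve, step
# interpolation) of one class given scores and binary truth.
averagePrecision <- function(scores, truth) {
  if (!any(truth)) {
    return(NA_real_)
  }
  ord <- order(-scores)
  truth <- truth[ord]
  tp <- cumsum(truth)
  precision <- tp / seq_along(truth)
  recall <- tp / sum(truth)
  d_recall <- diff(c(0, recall))
  sum(precision * d_recall)
}

multiclassMCC <- function(conf) {
  n <- sum(conf)
  correct <- sum(diag(conf))
  pred_tot <- colSums(conf)
  true_tot <- rowSums(conf)
  num <- correct * n - sum(true_tot * pred_tot)
  den <- sqrt(n^2 - sum(pred_tot^2)) * sqrt(n^2 - sum(true_tot^2))
  if (den == 0) {
    return(0)
  }
  num / den
}

#' Classification scores for transferred labels
#'
#' Confusion-matrix based scores of the label transfer on query cells whose
#' true label exists in the reference (cells from unseen populations are
#' excluded: they have no correct class). Per-class F1 and Jaccard are
#' averaged micro (pooled counts), macro (unweighted mean) and
#' rarity-weighted (weights proportional to 1 / n_l true query cells).
#' The Matthews correlation coefficient is rescaled to \[0, 1\] as
#' (MCC + 1) / 2 and the macro AUPRC averages one-vs-rest average precision
#' over classes using the probability columns.
#'
#' @param tr a [TransferResult-class].
#' @param trueLabels ground-truth query labels (aligned with \code{tr}).
#' @param unseenLabels labels excluded from scoring.
#' @return named list of `MetricScore`s: \code{accuracy}, \code{f1_micro},
#'   \code{f1_macro}, \code{f1_rarity}, \code{jaccard_micro},
#'   \code{jaccard_macro}, \code{jaccard_rarity}, \code{mcc01},
#'   \code{auprc_macro}.
#' @export
classificationScores <- function(tr, trueLabels, unseenLabels = character()) {
  truth <- as.character(trueLabels)
  keep <- !(truth %in% unseenLabels)
  assertThat(any(keep), "no scorable query cells")
  truth <- truth[keep]
  pred <- predictedLabels(tr)[keep]
  prob <- classProbabilities(tr)[keep, , drop = FALSE]
  classes <- transferClasses(tr)
  present <- intersect(classes, unique(truth))
  skipped <- setdiff(classes, present)
  conf <- table(
    factor(truth, levels = classes),
    factor(pred, levels = classes)
  )
  n <- sum(conf)
  tp <- diag(conf)
  fp <- colSums(conf) - tp
  fn <- rowSums(conf) - tp
  per_f1 <- ifelse(2 * tp + fp + fn > 0, 2 * tp / (2 * tp + fp + fn), 0)
  per_jacc <- ifelse(tp + fp + fn > 0, tp / (tp + fp + fn), 0)
  names(per_f1) <- names(per_jacc) <- classes
  idx <- match(present, classes)
  n_l <- rowSums(conf)[idx]
  w_rar <- (1 / n_l) / sum(1 / n_l)
  micro_f1 <- 2 * sum(tp) / (2 * sum(tp) + sum(fp) + sum(fn))
  micro_jacc <- sum(tp) / (sum(tp) + sum(fp) + sum(fn))
  note <- if (length(skipped)) {
    paste0("classes absent from query truth skipped: ",
      paste(skipped, collapse = ","))
  } else {
    character()
  }
  ap <- vapply(present, function(cl) {
    averagePrecision(prob[, cl], truth == cl)
  }, numeric(1))
  mk <- function(name, value) {
    metricScore(name, "classification", value, length(truth), note)
  }
  list(
    accuracy = mk("accuracy", mean(pred == truth)),
    f1_micro = mk("f1_micro", micro_f1),
    f1_macro = mk("f1_macro", mean(per_f1[idx])),
    f1_rarity = mk("f1_rarity", sum(w_rar * per_f1[idx])),
    jaccard_micro = mk("jaccard_micro", micro_jacc),
    jaccard_macro = mk("jaccard_macro", mean(per_jacc[idx])),
    jaccard_rarity = mk("jaccard_rarity", sum(w_rar * per_jacc[idx])),
    mcc01 = mk("mcc01", (multiclassMCC(conf) + 1) / 2),
    auprc_macro = mk("auprc_macro", mean(ap, na.rm = TRUE))
  )
}
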