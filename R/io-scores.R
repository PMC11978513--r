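metricCategories <- c("batch", "bio", "mapping", "classification", "unseen")

validateScoreTable <- function(table) {
  required <- c("dataset", "method", "metric", "category", "value")
  assertThat(
    is.data.frame(table) && all(required %in% colnames(table)),
    "score table must have columns: ", paste(required, collapse = ", ")
  )
  bad <- setdiff(unique(as.character(table$category)), metricCategories)
  assertThat(
    length(bad) == 0,
    "unknown metric category: ", paste(bad, collapse = ", "),
    " (expected one of ", paste(metricCategories, collapse = ", "), ")"
  )
  assertThat(
    is.numeric(table$value),
    "score table 'value' column must be numeric"
  )
  invisible(table)
}

#' Write / read benchmark score tables
#'
#' Score tables are long-format data frames with columns
#' \code{dataset}, \code{method}, \code{metric}, \code{category},
#' \code{value}, written as TSV. Missing values are preserved as \code{NA}
#' and flagged with a warning on read.
#'
#' @param table score table data frame.
#' @param path TSV path.
#' @return \code{writeScores}: the path, invisibly. \code{readScores}: the
#'   validated score table.
#' @export
writeScores <- function(table, path) {
  validateScoreTable(table)
  table <- table[, c("dataset", "method", "metric", "category", "value",
    setdiff(colnames(table), c("dataset", "method", "metric", "category", "value"))
  ), drop = FALSE]
  write.table(table, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    na = "NA"
  )
  invisible(path)
}

#' @rdname writeScores
#' @export
readScores <- function(path) {
  assertThat(file.exists(path), "no such score table: ", path)
  table <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validateScoreTable(table)
  n_missing <- sum(!is.finite(table$value))
  if (n_missing > 0) {
    warning(n_missing, " missing metric value(s) in ", path)
  }
  table
}
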