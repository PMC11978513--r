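# Minimal AnnData-on-disk (H5AD) layer built directly on rhdf5. Supports the
# subset of the format the benchmark needs: X as a dense array or CSR/CSC
# sparse group, obs/var data frames with plain or categorical columns, obsm
# dense arrays, and string sets in uns. Matrices are presented in R as
# cells x features.

h5attr <- function(file, name, attr) {
  fid <- rhdf5::H5Fopen(file)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  obj <- tryCatch(rhdf5::H5Oopen(fid, name), error = function(e) NULL)
  if (is.null(obj)) {
    return(NULL)
  }
  on.exit(rhdf5::H5Oclose(obj), add = TRUE)
  if (!rhdf5::H5Aexists(obj, attr)) {
    return(NULL)
  }
  aid <- rhdf5::H5Aopen(obj, attr)
  on.exit(rhdf5::H5Aclose(aid), add = TRUE)
  as.vector(rhdf5::H5Aread(aid))
}

writeH5Attr <- function(file, name, attr, value, asScalar = NULL) {
  fid <- rhdf5::H5Fopen(file)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  obj <- rhdf5::H5Oopen(fid, name)
  on.exit(rhdf5::H5Oclose(obj), add = TRUE)
  if (is.null(asScalar)) asScalar <- length(value) == 1L
  rhdf5::h5writeAttribute(value, obj, attr, variableLengthString = TRUE,
    asScalar = asScalar)
}

readH5Matrix <- function(file, name, n_obs, n_var) {
  contents <- rhdf5::h5ls(file)
  entry <- contents[contents$group == dirname2(name) &
    contents$name == basename(name), , drop = FALSE]
  if (!nrow(entry)) stop("no such H5AD entry: ", name, call. = FALSE)
  if (entry$otype[1] == "H5I_GROUP") {
    enc <- h5attr(file, name, "encoding-type")
    data <- as.numeric(rhdf5::h5read(file, paste0(name, "/data")))
    indices <- as.integer(rhdf5::h5read(file, paste0(name, "/indices")))
    indptr <- as.integer(rhdf5::h5read(file, paste0(name, "/indptr")))
    if (!is.null(enc) && grepl("csc", enc)) {
      m <- Matrix::sparseMatrix(
        i = indices + 1L, p = indptr, x = data,
        dims = c(n_obs, n_var)
      )
    } else { # csr: obs x var row-compressed == transpose in CSC
      m <- Matrix::t(Matrix::sparseMatrix(
        i = indices + 1L, p = indptr,
        x = data, dims = c(n_var, n_obs)
      ))
    }
    methods::as(m, "CsparseMatrix")
  } else {
    m <- rhdf5::h5read(file, name)
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    # h5py writes obs x var row-major; rhdf5 returns it transposed
    if (nrow(m) == n_var && ncol(m) == n_obs && n_var != n_obs) m <- t(m)
    if (nrow(m) != n_obs) m <- t(m)
    m
  }
}

dirname2 <- function(x) {
  d <- dirname(x)
  if (d == ".") "/" else d
}

readH5DataFrame <- function(file, name) {
  contents <- rhdf5::h5ls(file)
  cols <- contents[contents$group == name, , drop = FALSE]
  index_name <- h5attr(file, name, "_index")
  if (is.null(index_name)) index_name <- "_index"
  idx <- as.character(rhdf5::h5read(file, paste0(name, "/", index_name)))
  df <- data.frame(row.names = idx)
  for (i in seq_len(nrow(cols))) {
    cn <- cols$name[i]
    if (cn %in% c(index_name, "__categories")) next
    path <- paste0(name, "/", cn)
    if (cols$otype[i] == "H5I_GROUP") {
      codes <- as.integer(rhdf5::h5read(file, paste0(path, "/codes")))
      cats <- as.character(rhdf5::h5read(file, paste0(path, "/categories")))
      v <- factor(ifelse(codes < 0, NA, cats[codes + 1L]), levels = cats)
    } else {
      v <- as.vector(rhdf5::h5read(file, path))
      if (is.raw(v)) v <- as.integer(v)
    }
    df[[cn]] <- v
  }
  df
}

#' Read an H5AD file into a raw annotated cell matrix
#'
#' Loads counts (from \code{X} or a named layer), per-cell annotations and any
#' embeddings from an AnnData H5AD file and assembles a [CellMatrix-class]
#' together with the reference/query designation derived from
#' \code{queryBatches}.
#'
#' @param path H5AD file path.
#' @param batchKey,labelKey names of the obs columns holding batch and label.
#' @param queryBatches character vector of batches forming the query.
#' @param unseenLabels labels designated as unseen query populations.
#' @param layer optional layer name holding counts (default: \code{X}).
#' @param roundCounts policy for non-integer counts: \code{"error"} (default)
#'   or \code{"round"} (round with a warning).
#' @return list with elements \code{cells} ([CellMatrix-class]),
#'   \code{isQuery} (logical per cell), \code{embeddings} (named list of
#'   obsm matrices) and \code{obs} (full annotation data frame).
#' @export
readDataset <- function(path, batchKey, labelKey, queryBatches = character(),
                        unseenLabels = character(), layer = NULL,
                        roundCounts = c("error", "round")) {
  roundCounts <- match.arg(roundCounts)
  assertThat(file.exists(path), "file not found: ", path)
  obs <- readH5DataFrame(path, "/obs")
  var <- readH5DataFrame(path, "/var")
  n_obs <- nrow(obs)
  n_var <- nrow(var)
  if (n_obs == 0 || n_var == 0) stop("empty matrix in ", path, call. = FALSE)
  for (key in c(batchKey, labelKey)) {
    if (!key %in% colnames(obs)) {
      stop(
        "obs column '", key, "' not found; available: ",
        paste(colnames(obs), collapse = ", "),
        call. = FALSE
      )
    }
  }
  xname <- if (is.null(layer)) "/X" else paste0("/layers/", layer)
  m <- readH5Matrix(path, xname, n_obs, n_var)
  vals <- if (inherits(m, "sparseMatrix")) m@x else m
  if (any(abs(vals - round(vals)) > 1e-8)) {
    if (roundCounts == "error") {
      stop("counts are not integers; set roundCounts = 'round' to round",
        call. = FALSE
      )
    }
    warning("rounding non-integer counts")
    if (inherits(m, "sparseMatrix")) m@x <- round(m@x) else m <- round(m)
  }
  dimnames(m) <- list(rownames(obs), rownames(var))
  cells <- CellMatrix(m, batch = obs[[batchKey]], label = obs[[labelKey]])
  embeddings <- list()
  contents <- rhdf5::h5ls(path)
  if ("/obsm" %in% paste0(contents$group, "/", contents$name) ||
    any(contents$group == "/obsm")) {
    for (nm in contents$name[contents$group == "/obsm"]) {
      em <- readH5Matrix(path, paste0("/obsm/", nm), n_obs, -1L)
      rownames(em) <- rownames(obs)
      embeddings[[nm]] <- em
    }
  }
  uns_unseen <- character()
  if (any(contents$group == "/uns" & contents$name == "unseen_labels")) {
    uns_unseen <- as.character(rhdf5::h5read(path, "/uns/unseen_labels"))
  }
  list(
    cells = cells,
    isQuery = as.character(obs[[batchKey]]) %in% as.character(queryBatches),
    embeddings = embeddings,
    obs = obs,
    unseenLabels = unique(c(as.character(unseenLabels), uns_unseen))
  )
}

writeH5Column <- function(file, group, name, value) {
  path <- paste0(group, "/", name)
  if (is.factor(value)) {
    rhdf5::h5createGroup(file, path)
    rhdf5::h5write(as.integer(value) - 1L, file, paste0(path, "/codes"))
    rhdf5::h5write(levels(value), file, paste0(path, "/categories"),
      variableLengthString = TRUE
    )
    writeH5Attr(file, path, "encoding-type", "categorical")
    writeH5Attr(file, path, "encoding-version", "0.2.0")
    writeH5Attr(file, path, "ordered", 0L)
  } else if (is.character(value)) {
    rhdf5::h5write(value, file, path, variableLengthString = TRUE)
    writeH5Attr(file, path, "encoding-type", "string-array")
    writeH5Attr(file, path, "encoding-version", "0.2.0")
  } else {
    rhdf5::h5write(value, file, path)
    writeH5Attr(file, path, "encoding-type", "array")
    writeH5Attr(file, path, "encoding-version", "0.2.0")
  }
}

writeH5DataFrame <- function(file, name, df) {
  rhdf5::h5createGroup(file, name)
  rhdf5::h5write(rownames(df), file, paste0(name, "/_index"),
    variableLengthString = TRUE
  )
  for (cn in colnames(df)) writeH5Column(file, name, cn, df[[cn]])
  writeH5Attr(file, name, "encoding-type", "dataframe")
  writeH5Attr(file, name, "encoding-version", "0.2.0")
  writeH5Attr(file, name, "_index", "_index")
  writeH5Attr(file, name, "column-order", colnames(df), asScalar = FALSE)
}

#' Write a SplitDataset (plus optional embeddings) to H5AD
#'
#' Writes reference and query cells into a single AnnData-format file with
#' obs columns \code{batch}, \code{label} and \code{is_query}, unseen labels
#' in \code{uns/unseen_labels}, and optional obsm embeddings.
#'
#' @param ds a [SplitDataset-class].
#' @param path output H5AD path (overwritten).
#' @param embeddings optional named list of (n_ref + n_query) x d matrices
#'   written to obsm.
#' @param sparse write X as CSR sparse (default TRUE).
#' @return \code{path}, invisibly.
#' @export
writeH5AD <- function(ds, path, embeddings = list(), sparse = TRUE) {
  ref <- reference(ds)
  qry <- query(ds)
  m <- rbind(
    methods::as(counts(ref), "CsparseMatrix"),
    methods::as(counts(qry), "CsparseMatrix")
  )
  obs <- data.frame(
    row.names = make.unique(c(cellIds(ref), cellIds(qry))),
    batch = factor(c(as.character(cellBatch(ref)), as.character(cellBatch(qry)))),
    label = factor(c(as.character(cellLabel(ref)), as.character(cellLabel(qry)))),
    is_query = c(rep(0L, nCells(ref)), rep(1L, nCells(qry)))
  )
  var <- data.frame(row.names = featureIds(ref))
  var$feature_id <- featureIds(ref)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  if (sparse) {
    # CSR of obs x var == CSC of its transpose
    mt <- Matrix::t(m)
    rhdf5::h5createGroup(path, "/X")
    rhdf5::h5write(mt@x, path, "/X/data")
    rhdf5::h5write(mt@i, path, "/X/indices")
    rhdf5::h5write(mt@p, path, "/X/indptr")
    writeH5Attr(path, "/X", "encoding-type", "csr_matrix")
    writeH5Attr(path, "/X", "encoding-version", "0.1.0")
    writeH5Attr(path, "/X", "shape", c(nrow(m), ncol(m)))
  } else {
    rhdf5::h5write(as.matrix(m), path, "/X")
    writeH5Attr(path, "/X", "encoding-type", "array")
    writeH5Attr(path, "/X", "encoding-version", "0.2.0")
  }
  writeH5DataFrame(path, "/obs", obs)
  writeH5DataFrame(path, "/var", var)
  rhdf5::h5createGroup(path, "/obsm")
  for (nm in names(embeddings)) {
    rhdf5::h5write(as.matrix(embeddings[[nm]]), path, paste0("/obsm/", nm))
  }
  rhdf5::h5createGroup(path, "/uns")
  if (length(unseenLabels(ds))) {
    rhdf5::h5write(unseenLabels(ds), path, "/uns/unseen_labels",
      variableLengthString = TRUE
    )
  }
  writeH5Attr(path, "/", "encoding-type", "anndata")
  writeH5Attr(path, "/", "encoding-version", "0.1.0")
  rhdf5::h5closeAll()
  invisible(path)
}
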