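#' Cells-by-features omics matrix
#'
#' Light container for a single-modality count or normalized matrix: a numeric
#' cells x features matrix plus unique cell and feature identifiers and a
#' modality tag (`"rna"` or `"atac"`). All preprocessing operations consume
#' and return this class so that provenance (modality, normalization state)
#' travels with the values.
#'
#' @param values numeric matrix, cells in rows, features in columns.
#' @param cell_ids character vector of unique cell identifiers (defaults to
#'   existing rownames or `cell_1..cell_N`).
#' @param feature_ids character vector of unique feature identifiers.
#' @param modality `"rna"` or `"atac"`.
#' @param normalized logical flag recording whether the values have been
#'   normalized (log-normalized / TF-IDF transformed).
#' @return an `omics_matrix` object.
#' @export
#' @examples
#' m <- omics_matrix(matrix(rpois(20, 3), 4, 5), modality = "rna")
#' dim(m$values)
omics_matrix <- function(values, cell_ids = NULL, feature_ids = NULL,
                         modality = c("rna", "atac"), normalized = FALSE) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  cell_ids <- cell_ids %||% rownames(values) %||%
    paste0("cell_", seq_len(nrow(values)))
  feature_ids <- feature_ids %||% colnames(values) %||%
    paste0("feat_", seq_len(ncol(values)))
  if (length(cell_ids) != nrow(values)) {
    stop_hamgcn("cell_ids length must equal number of rows")
  }
  if (length(feature_ids) != ncol(values)) {
    stop_hamgcn("feature_ids length must equal number of columns")
  }
  if (anyDuplicated(cell_ids)) stop_hamgcn("cell_ids must be unique")
  if (anyDuplicated(feature_ids)) stop_hamgcn("feature_ids must be unique")
  assert_finite(values, "omics matrix")
  if (!normalized && any(values < 0)) {
    stop_hamgcn("raw count values must be non-negative",
                class = "hamgcn_invalid_input")
  }
  dimnames(values) <- list(cell_ids, feature_ids)
  structure(
    list(values = values, cell_ids = as.character(cell_ids),
         feature_ids = as.character(feature_ids), modality = modality,
         normalized = normalized),
    class = "omics_matrix"
  )
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> %s: %d cells x %d features (%s)\n",
              x$modality, nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Read an omics matrix from MatrixMarket or dense TSV
#'
#' Two on-disk layouts are supported: 10x-style MatrixMarket triplets
#' (`matrix.mtx` stored features x cells, as CellRanger writes it, with
#' `features.tsv` and `barcodes.tsv` sidecars) and a dense TSV whose header
#' row holds feature ids and whose first column holds cell ids.
#'
#' @param path for `format = "mtx"`, the directory holding `matrix.mtx`,
#'   `features.tsv`, `barcodes.tsv`; for `format = "tsv"` the file itself.
#' @param modality `"rna"` or `"atac"`.
#' @param format `"mtx"` or `"tsv"`; guessed from `path` when missing.
#' @return an [omics_matrix()].
#' @export
read_omics <- function(path, modality = c("rna", "atac"),
                       format = c("auto", "mtx", "tsv")) {
  modality <- match.arg(modality)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "mtx" else "tsv"
  }
  if (format == "mtx") {
    m <- Matrix::readMM(file.path(path, "matrix.mtx"))
    feats <- read.delim(file.path(path, "features.tsv"), header = FALSE,
                        stringsAsFactors = FALSE)[[1]]
    cells <- read.delim(file.path(path, "barcodes.tsv"), header = FALSE,
                        stringsAsFactors = FALSE)[[1]]
    values <- t(as.matrix(m))   # stored features x cells
    omics_matrix(values, cell_ids = cells, feature_ids = feats,
                 modality = modality)
  } else {
    df <- read.delim(path, header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
    values <- as.matrix(df[, -1, drop = FALSE])
    omics_matrix(values, cell_ids = df[[1]], feature_ids = colnames(df)[-1],
                 modality = modality)
  }
}

#' Write an omics matrix to disk
#'
#' @param x an [omics_matrix()].
#' @param path output directory (`mtx`) or file (`tsv`).
#' @param format `"mtx"` (features x cells triplets + sidecars) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_omics <- function(x, path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(Matrix::Matrix(t(x$values), sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    writeLines(x$feature_ids, file.path(path, "features.tsv"))
    writeLines(x$cell_ids, file.path(path, "barcodes.tsv"))
  } else {
    df <- data.frame(cell_id = x$cell_ids, x$values, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Subset an omics matrix by cells and/or features
#'
#' @param x an [omics_matrix()].
#' @param cells,features logical mask, integer index, or id vector; `NULL`
#'   keeps everything.
#' @return an [omics_matrix()].
#' @export
subset_omics <- function(x, cells = NULL, features = NULL) {
  ci <- resolve_index(cells, x$cell_ids)
  fi <- resolve_index(features, x$feature_ids)
  omics_matrix(x$values[ci, fi, drop = FALSE],
               cell_ids = x$cell_ids[ci], feature_ids = x$feature_ids[fi],
               modality = x$modality, normalized = x$normalized)
}

resolve_index <- function(idx, ids) {
  if (is.null(idx)) return(seq_along(ids))
  if (is.logical(idx)) {
    if (length(idx) != length(ids)) stop_hamgcn("mask length mismatch")
    return(which(idx))
  }
  if (is.character(idx)) {
    pos <- match(idx, ids)
    if (anyNA(pos)) stop_hamgcn("unknown ids in subset")
    return(pos)
  }
  as.integer(idx)
}
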