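#' Undirected simple graph over cells
#'
#' Edge-list container used by every message-passing step: `n_nodes` cells
#' and a two-column integer matrix of 0-based unordered pairs, stored once
#' per pair with `from < to` and sorted lexicographically. No self-loops, no
#' duplicates.
#'
#' @param n_nodes number of cells.
#' @param edges two-column matrix (or data frame) of 0-based node ids.
#' @return a `cell_graph` object.
#' @export
cell_graph <- function(n_nodes, edges) {
  edges <- as.matrix(edges)
  if (length(edges) == 0) {
    edges <- matrix(integer(), ncol = 2)
  }
  storage.mode(edges) <- "integer"
  if (ncol(edges) != 2) stop_hamgcn("edges must have two columns")
  if (nrow(edges) > 0) {
    if (any(edges < 0) || any(edges >= n_nodes)) {
      stop_hamgcn("edge endpoint out of range")
    }
    if (any(edges[, 1] == edges[, 2])) stop_hamgcn("self-loops not allowed")
    swap <- edges[, 1] > edges[, 2]
    edges[swap, ] <- edges[swap, 2:1]
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  colnames(edges) <- c("from", "to")
  structure(list(n_nodes = as.integer(n_nodes), edges = edges),
            class = "cell_graph")
}

#' @export
print.cell_graph <- function(x, ...) {
  cat(sprintf("<cell_graph> %d nodes, %d undirected edges\n",
              x$n_nodes, nrow(x$edges)))
  invisible(x)
}

#' Validate cell-graph invariants
#' @param g a [cell_graph()].
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_cell_graph <- function(g) {
  e <- g$edges
  stopifnot(is.matrix(e), ncol(e) == 2)
  if (nrow(e) > 0) {
    if (any(e[, 1] >= e[, 2])) stop_hamgcn("edges must satisfy from < to")
    if (any(e < 0) || any(e >= g$n_nodes)) stop_hamgcn("endpoint out of range")
    if (anyDuplicated(e)) stop_hamgcn("duplicate edges")
  }
  invisible(TRUE)
}

#' Number of edges
#' @param g a [cell_graph()].
#' @return integer edge count.
#' @export
n_edges <- function(g) nrow(g$edges)

#' Pairwise distance matrix under a named metric
#' @noRd
dist_matrix <- function(x, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  if (metric == "euclidean") {
    as.matrix(stats::dist(x))
  } else {
    nrm <- sqrt(rowSums(x^2))
    xn <- x / ifelse(nrm > 0, nrm, 1)
    sim <- tcrossprod(xn)
    sim[nrm == 0, ] <- 0
    sim[, nrm == 0] <- 0
    d <- 1 - sim
    diag(d) <- 0
    d
  }
}

#' k-nearest-neighbor indices per row with deterministic tie-breaks
#'
#' Ties in distance are broken by lower node id; self is never a neighbor.
#' @noRd
knn_indices <- function(d, k) {
  n <- nrow(d)
  if (k >= n) stop_hamgcn("k must be smaller than the number of nodes")
  out <- matrix(0L, n, k)
  ids <- seq_len(n)
  for (i in seq_len(n)) {
    di <- d[i, ]
    di[i] <- Inf
    ord <- order(di, ids)
    out[i, ] <- ord[seq_len(k)]
  }
  out
}

#' k-nearest-neighbor graph
#'
#' Builds the directed k-NN relation under the chosen metric and
#' symmetrizes by union, yielding an undirected simple graph. Distance ties
#' are broken by lower node id, so the result is deterministic.
#'
#' @param embedding cells x d numeric matrix.
#' @param k neighbors per node; must be `< nrow(embedding)`.
#' @param metric `"euclidean"` or `"cosine"`.
#' @return a [cell_graph()].
#' @export
#' @examples
#' emb <- matrix(c(0, 1, 10), ncol = 1)
#' knn_graph(emb, k = 1)$edges
knn_graph <- function(embedding, k, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  d <- dist_matrix(embedding, metric)
  knn_graph_from_dist(d, k)
}

knn_graph_from_dist <- function(d, k) {
  nn <- knn_indices(d, k)
  n <- nrow(d)
  from <- rep(seq_len(n), each = ncol(nn)) - 1L
  to <- as.integer(t(nn)) - 1L
  cell_graph(n, cbind(from, to))
}

#' Per-cell modality weights by cross-modality prediction
#'
#' Simplified weighted-nearest-neighbor scheme: for each cell and each
#' modality, the cell's profile in that modality is predicted (a) from the
#' mean of its k nearest neighbors in the *same* modality's embedding and
#' (b) from the mean of its k nearest neighbors in the *other* modality's
#' embedding. A modality whose within-modality prediction beats the
#' cross-modality prediction carries information the other modality lacks;
#' the difference of the two prediction errors is the modality affinity, and
#' per-cell weights are the softmax of the two affinities (an exponential
#' kernel normalized to sum to one).
#'
#' @param rna_embed,atac_embed cells x d numeric matrices (same cell count,
#'   dimensions may differ).
#' @param k neighbors used for prediction (default 20).
#' @return tibble with columns `cell`, `w_rna`, `w_atac` (rows sum to 1).
#' @export
wnn_weights <- function(rna_embed, atac_embed, k = 20) {
  rna_embed <- as.matrix(rna_embed)
  atac_embed <- as.matrix(atac_embed)
  n <- nrow(rna_embed)
  if (nrow(atac_embed) != n) stop_hamgcn("modality cell counts differ")
  d_rna <- dist_matrix(rna_embed, "euclidean")
  d_atac <- dist_matrix(atac_embed, "euclidean")
  nn_rna <- knn_indices(d_rna, k)
  nn_atac <- knn_indices(d_atac, k)
  pred_err <- function(x, nn) {
    pred <- t(apply(nn, 1L, function(js) colMeans(x[js, , drop = FALSE])))
    if (ncol(x) == 1) pred <- matrix(pred, ncol = 1)
    sqrt(rowSums((x - pred)^2))
  }
  e_rna_within <- pred_err(rna_embed, nn_rna)
  e_rna_cross <- pred_err(rna_embed, nn_atac)
  e_atac_within <- pred_err(atac_embed, nn_atac)
  e_atac_cross <- pred_err(atac_embed, nn_rna)
  scale_i <- (e_rna_within + e_rna_cross + e_atac_within + e_atac_cross) / 4
  scale_i[scale_i <= 0] <- 1
  a_rna <- (e_rna_cross - e_rna_within) / scale_i
  a_atac <- (e_atac_cross - e_atac_within) / scale_i
  m <- pmax(a_rna, a_atac)
  w_rna <- exp(a_rna - m) / (exp(a_rna - m) + exp(a_atac - m))
  tibble::tibble(cell = seq_len(n), w_rna = w_rna, w_atac = 1 - w_rna)
}

#' Consensus graph from weighted fused distances
#'
#' Per-modality distances are z-scaled within each cell's row (so the two
#' modalities contribute on comparable scales), fused with the per-cell
#' modality weights, and a union-symmetrized k-NN graph is built on the
#' fused distances.
#'
#' @param rna_embed,atac_embed cells x d matrices.
#' @param weights tibble from [wnn_weights()] (columns `w_rna`, `w_atac`).
#' @param k neighbors for the consensus graph (default 15).
#' @param rna_metric,atac_metric distance metrics per modality; defaults
#'   euclidean for RNA, cosine for the ATAC (LSI) embedding.
#' @return a [cell_graph()].
#' @export
wnn_consensus_graph <- function(rna_embed, atac_embed, weights, k = 15,
                                rna_metric = "euclidean",
                                atac_metric = "cosine") {
  d_rna <- dist_matrix(rna_embed, rna_metric)
  d_atac <- dist_matrix(atac_embed, atac_metric)
  z_rows <- function(d) {
    n <- nrow(d)
    for (i in seq_len(n)) {
      r <- d[i, -i]
      s <- sd(r)
      d[i, ] <- if (is.finite(s) && s > 0) (d[i, ] - mean(r)) / s else 0
    }
    d
  }
  zr <- z_rows(d_rna)
  za <- z_rows(d_atac)
  fused <- weights$w_rna * zr + weights$w_atac * za
  diag(fused) <- 0
  knn_graph_from_dist(fused, k)
}

#' Symmetrically normalized adjacency with self-loops
#'
#' Returns the sparse propagation operator
#' \eqn{\tilde{D}^{-1/2} (A + I) \tilde{D}^{-1/2}} used by every graph
#' convolution.
#'
#' @param g a [cell_graph()].
#' @return a symmetric sparse `Matrix`.
#' @export
normalized_adjacency <- function(g) {
  n <- g$n_nodes
  e <- g$edges
  i <- c(e[, 1] + 1L, e[, 2] + 1L, seq_len(n))
  j <- c(e[, 2] + 1L, e[, 1] + 1L, seq_len(n))
  a <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(a)
  dinv <- 1 / sqrt(deg)
  Matrix::Diagonal(x = dinv) %*% a %*% Matrix::Diagonal(x = dinv)
}

#' Write / read an edge list (two-column 0-based TSV + JSON sidecar)
#'
#' @param g a [cell_graph()].
#' @param path output TSV; sidecar metadata goes to `<path>.json`.
#' @param meta named list merged into the sidecar (k, metric, seed, ...).
#' @return `path` invisibly, or the re-read [cell_graph()].
#' @export
write_cell_graph <- function(g, path, meta = list()) {
  utils::write.table(g$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(c(list(n_nodes = g$n_nodes, n_edges = n_edges(g)), meta),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cell_graph
#' @export
read_cell_graph <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  edges <- if (file.size(path) > 0) {
    as.matrix(read.delim(path, header = FALSE))
  } else {
    matrix(integer(), ncol = 2)
  }
  cell_graph(side$n_nodes, edges)
}
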