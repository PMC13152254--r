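#' Log-normalize RNA counts
#'
#' Each cell's counts are divided by the cell total, multiplied by
#' `scale_factor`, and mapped through `log(1 + x)` — the standard
#' log-normalization for scRNA-seq with the conventional scale factor of
#' 10,000. Cells with zero total counts are kept as all-zero rows with a
#' warning; dropping them is an explicit QC decision left to the caller.
#'
#' @param counts an [omics_matrix()] with `modality = "rna"` and raw counts.
#' @param scale_factor positive scalar, default `1e4`.
#' @return a normalized [omics_matrix()].
#' @export
#' @examples
#' m <- omics_matrix(matrix(c(1, 1, 2, 0, 3, 1), 2, 3, byrow = TRUE))
#' normalize_rna(m)$values
normalize_rna <- function(counts, scale_factor = 1e4) {
  stopifnot(inherits(counts, "omics_matrix"))
  if (counts$modality != "rna") stop_hamgcn("normalize_rna expects modality 'rna'")
  if (any(counts$values < 0)) {
    stop_hamgcn("negative counts", class = "hamgcn_invalid_input")
  }
  if (scale_factor <= 0) stop_hamgcn("scale_factor must be positive")
  totals <- rowSums(counts$values)
  zero <- totals == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with zero total counts kept as zero rows")
  }
  denom <- ifelse(zero, 1, totals)
  out <- log1p(counts$values / denom * scale_factor)
  omics_matrix(out, counts$cell_ids, counts$feature_ids,
               modality = "rna", normalized = TRUE)
}

#' Center and scale features to zero mean and unit variance
#'
#' Per-feature standardization (sample standard deviation, denominator
#' `n - 1`). Constant features map to all-zero columns rather than NaN.
#'
#' @param x an [omics_matrix()] (typically log-normalized).
#' @return an [omics_matrix()] with standardized columns.
#' @export
scale_features <- function(x) {
  stopifnot(inherits(x, "omics_matrix"))
  v <- x$values
  mu <- colMeans(v)
  s <- apply(v, 2L, sd)
  s[s == 0 | !is.finite(s)] <- Inf   # constant columns -> 0 after division
  out <- sweep(sweep(v, 2L, mu, "-"), 2L, s, "/")
  omics_matrix(out, x$cell_ids, x$feature_ids, modality = x$modality,
               normalized = TRUE)
}

#' Select highly variable features by standardized variance
#'
#' Variance-stabilizing selection: a second-degree polynomial is fit to
#' log10(variance) against log10(mean) across features (the mean-variance
#' trend), counts are standardized by the trend-predicted standard deviation
#' with clipping at `sqrt(N)`, and features are ranked by the variance of the
#' clipped standardized values. Deterministic given the input; ties broken by
#' feature order.
#'
#' @param x an [omics_matrix()] of raw or log-normalized counts. Selection is
#'   conventionally run on raw counts; any non-negative matrix is accepted.
#' @param n_features number of features to keep (default 2000).
#' @return a `feature_selection` object (see [feature_selection()]).
#' @export
select_hvg <- function(x, n_features = 2000) {
  stopifnot(inherits(x, "omics_matrix"))
  f <- ncol(x$values)
  if (n_features > f) stop_hamgcn("n_features exceeds feature count")
  v <- x$values
  n <- nrow(v)
  mu <- colMeans(v)
  va <- apply(v, 2L, var)
  usable <- mu > 0 & va > 0
  std_var <- numeric(f)
  if (sum(usable) >= 3) {
    lm10 <- log10(mu[usable])
    lv10 <- log10(va[usable])
    ## a quadratic over a near-degenerate mean range is ill-conditioned;
    ## fall back to a constant trend when means barely vary
    fit <- if (diff(range(lm10)) < 0.5) {
      lm(lv10 ~ 1)
    } else {
      lm(lv10 ~ lm10 + I(lm10^2))
    }
    pred_sd <- sqrt(10^as.numeric(predict(fit)))
    clip <- sqrt(n)
    idx <- which(usable)
    for (j in seq_along(idx)) {
      z <- (v[, idx[j]] - mu[idx[j]]) / pred_sd[j]
      z <- pmin(pmax(z, -clip), clip)
      std_var[idx[j]] <- sum((z - mean(z))^2) / (n - 1)
    }
  } else {
    std_var[usable] <- va[usable]
  }
  ord <- order(-std_var, seq_len(f))
  sel <- x$feature_ids[ord[seq_len(n_features)]]
  feature_selection(sel, method = "hvg_vst", derived_from = x$cell_ids)
}

#' Ordered feature selection record
#'
#' @param selected_ids ordered character vector of selected feature ids.
#' @param method how the selection was produced.
#' @param derived_from ids of the cells the selection was computed on (the
#'   training cells, for leakage-sensitive methods).
#' @param stats optional tibble of per-feature statistics.
#' @return a `feature_selection` object.
#' @export
feature_selection <- function(selected_ids,
                              method = c("hvg_vst", "wilcoxon_de", "variance",
                                         "mutual_info", "rfe"),
                              derived_from = character(), stats = NULL) {
  method <- match.arg(method)
  structure(list(selected_ids = as.character(selected_ids), method = method,
                 derived_from = as.character(derived_from), stats = stats),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("<feature_selection> %s: %d features (from %d cells)\n",
              x$method, length(x$selected_ids), length(x$derived_from)))
  invisible(x)
}

#' Write / read a feature selection (id list + JSON sidecar)
#' @param x a `feature_selection`.
#' @param path output text file; sidecar written to `<path>.json`.
#' @return `path` invisibly, or the re-read object.
#' @export
write_feature_selection <- function(x, path) {
  writeLines(x$selected_ids, path)
  jsonlite::write_json(
    list(method = x$method, n_selected = length(x$selected_ids),
         n_train = length(x$derived_from)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_feature_selection
#' @export
read_feature_selection <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  feature_selection(readLines(path), method = side$method)
}

#' ATAC quality-control filter on nucleosome signal and TSS enrichment
#'
#' Keeps cells whose nucleosome signal is at most 2 and TSS enrichment at
#' least 2 (cells failing either strict inequality — nucleosome signal > 2 or
#' TSS enrichment < 2 — are removed; boundary values are kept). Cells with a
#' missing metric are dropped with a warning.
#'
#' @param qc data frame with columns `nucleosome_signal` and `tss_enrichment`
#'   (one row per cell), e.g. as read from a QC TSV.
#' @param ns_max,tss_min filter thresholds; defaults 2 and 2.
#' @return logical keep-mask over cells.
#' @export
qc_filter_atac <- function(qc, ns_max = 2, tss_min = 2) {
  ns <- qc$nucleosome_signal
  tss <- qc$tss_enrichment
  bad <- !is.finite(ns) | !is.finite(tss)
  if (any(bad)) warning(sum(bad), " cell(s) with missing QC metrics dropped")
  keep <- !bad & ns <= ns_max & tss >= tss_min
  keep
}

#' TF-IDF transform for peak accessibility matrices
#'
#' Term frequency is each peak's count divided by the cell total
#' (`tf = "total"`) or a 0/1 detection indicator (`tf = "binary"`); inverse
#' document frequency is `log(1 + N / df)` with `df` the number of cells in
#' which the peak is detected. The output entry is `log(1 + TF * IDF)`, the
#' log1p dialect that maps structural zeros to exact zeros. Peaks detected in
#' no cell give all-zero columns; cells with zero totals give zero rows with
#' a warning.
#'
#' @param peaks an [omics_matrix()] with `modality = "atac"`.
#' @param tf `"total"` (count / cell total, default) or `"binary"`.
#' @return a normalized [omics_matrix()].
#' @export
tfidf_transform <- function(peaks, tf = c("total", "binary")) {
  stopifnot(inherits(peaks, "omics_matrix"))
  tf <- match.arg(tf)
  if (peaks$modality != "atac") stop_hamgcn("tfidf_transform expects modality 'atac'")
  v <- peaks$values
  if (any(v < 0)) stop_hamgcn("negative counts", class = "hamgcn_invalid_input")
  n <- nrow(v)
  totals <- rowSums(v)
  zero <- totals == 0
  if (any(zero)) warning(sum(zero), " cell(s) with zero total counts give zero rows")
  tfm <- if (tf == "total") {
    v / ifelse(zero, 1, totals)
  } else {
    (v > 0) * 1
  }
  df <- colSums(v > 0)
  idf <- ifelse(df > 0, log(1 + n / df), 0)
  out <- log1p(sweep(tfm, 2L, idf, "*"))
  omics_matrix(out, peaks$cell_ids, peaks$feature_ids, modality = "atac",
               normalized = TRUE)
}

#' Latent semantic indexing: truncated SVD scores
#'
#' Truncated singular value decomposition of the TF-IDF matrix; returns the
#' left singular vectors scaled by the singular values (`U diag(s)`)
#' restricted to the leading components. The sign of each component is fixed
#' so its largest-magnitude feature loading is positive, making the output
#' deterministic.
#'
#' @param tfidf an [omics_matrix()] (or plain matrix) of TF-IDF values.
#' @param n_components number of components (default 50).
#' @return cells x `n_components` numeric matrix with attribute `"d"`
#'   (singular values) and `"v"` (feature loadings).
#' @export
lsi_reduce <- function(tfidf, n_components = 50) {
  v <- if (inherits(tfidf, "omics_matrix")) tfidf$values else as.matrix(tfidf)
  if (n_components > min(dim(v))) {
    stop_hamgcn("n_components exceeds min(cells, features)")
  }
  sv <- svd(v, nu = n_components, nv = n_components)
  fix_svd_signs(sv, n_components, rownames(v))
}

#' Principal-component scores of a centered matrix
#'
#' Plumbing for graph construction: truncated SVD of the column-centered
#' matrix, returning `U diag(s)` scores with the same deterministic sign
#' convention as [lsi_reduce()].
#'
#' @inheritParams lsi_reduce
#' @param x matrix or [omics_matrix()].
#' @return cells x `n_components` score matrix.
#' @export
pca_reduce <- function(x, n_components = 50) {
  v <- if (inherits(x, "omics_matrix")) x$values else as.matrix(x)
  if (n_components > min(dim(v))) {
    stop_hamgcn("n_components exceeds min(cells, features)")
  }
  vc <- sweep(v, 2L, colMeans(v), "-")
  sv <- svd(vc, nu = n_components, nv = n_components)
  fix_svd_signs(sv, n_components, rownames(v))
}

fix_svd_signs <- function(sv, k, row_ids) {
  u <- sv$u[, seq_len(k), drop = FALSE]
  vv <- sv$v[, seq_len(k), drop = FALSE]
  d <- sv$d[seq_len(k)]
  for (j in seq_len(k)) {
    i <- which.max(abs(vv[, j]))
    if (vv[i, j] < 0) {
      vv[, j] <- -vv[, j]
      u[, j] <- -u[, j]
    }
  }
  scores <- sweep(u, 2L, d, "*")
  rownames(scores) <- row_ids
  attr(scores, "d") <- d
  attr(scores, "v") <- vv
  scores
}

#' Vectorized two-sided Wilcoxon rank-sum tests across features
#'
#' Normal approximation with tie correction and continuity correction,
#' matching `stats::wilcox.test(exact = FALSE, correct = TRUE)`.
#'
#' @param v numeric matrix (cells x features).
#' @param g1 logical mask for group 1 rows (rest are group 2).
#' @return numeric vector of two-sided p-values, one per feature.
#' @noRd
rank_sum_pvalues <- function(v, g1) {
  n1 <- sum(g1)
  n2 <- nrow(v) - n1
  n <- n1 + n2
  p <- numeric(ncol(v))
  for (j in seq_len(ncol(v))) {
    r <- rank(v[, j])
    w <- sum(r[g1]) - n1 * (n1 + 1) / 2      # Mann-Whitney U for group 1
    tie_tab <- table(v[, j])
    tie_term <- sum(tie_tab^3 - tie_tab)
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) { p[j] <- 1; next }
    z <- w - n1 * n2 / 2
    corr <- sign(z) * 0.5
    p[j] <- 2 * pnorm(abs(z - corr) / sqrt(sigma2), lower.tail = FALSE)
    p[j] <- min(1, p[j])
  }
  p
}

#' Training-set-restricted Wilcoxon differential feature selection
#'
#' For each feature, a two-sided Wilcoxon rank-sum test between the two
#' groups restricted to training cells, with Benjamini-Hochberg adjustment;
#' features with adjusted p below `alpha` are selected, ordered by adjusted
#' p-value. The selection depends only on training cells, so features chosen
#' on the training set can be frozen and applied to validation/test cells
#' without information leakage.
#'
#' @param x an [omics_matrix()].
#' @param groups per-cell group labels (exactly two levels among train cells).
#' @param train_mask logical mask (or cell-id vector) marking training cells.
#' @param alpha BH-adjusted p-value cutoff (default 0.05).
#' @return a `feature_selection` with per-feature statistics in `$stats`.
#' @export
wilcoxon_de <- function(x, groups, train_mask, alpha = 0.05) {
  stopifnot(inherits(x, "omics_matrix"))
  idx <- resolve_index(train_mask, x$cell_ids)
  v <- x$values[idx, , drop = FALSE]
  g <- as.factor(as.character(groups[idx]))
  lev <- levels(droplevels(g))
  if (length(lev) != 2) {
    stop_hamgcn("exactly two groups required among training cells")
  }
  g1 <- g == lev[1]
  if (sum(g1) == 0 || sum(!g1) == 0) stop_hamgcn("one group is empty")
  p <- rank_sum_pvalues(v, g1)
  padj <- p.adjust(p, method = "BH")
  stats_tbl <- tibble::tibble(
    feature_id = x$feature_ids,
    p_value = p, p_adjusted = padj,
    mean_diff = colMeans(v[g1, , drop = FALSE]) -
      colMeans(v[!g1, , drop = FALSE])
  )
  sel <- stats_tbl$feature_id[padj < alpha]
  sel <- sel[order(padj[padj < alpha], match(sel, x$feature_ids))]
  feature_selection(sel, method = "wilcoxon_de",
                    derived_from = x$cell_ids[idx], stats = stats_tbl)
}
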