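#' Preprocess a paired multiome into classifier features and a cell graph
#'
#' The standard wiring: RNA counts are log-normalized (scale factor 10,000),
#' restricted to highly variable genes, scaled, and reduced by PCA; ATAC
#' counts are optionally QC-filtered, TF-IDF transformed and reduced by LSI.
#' Modality k-NN graphs feed the weighted-nearest-neighbor modality weights
#' (k = 20) and the consensus k = 15 graph. Classifier features are either
#' the concatenated standardized embeddings (`features = "reduced"`,
#' default) or training-set Wilcoxon-selected genes plus peaks
#' (`features = "de"`), in which case `train_idx` and `labels` are required
#' and selection sees only training cells.
#'
#' @param rna,atac raw-count [omics_matrix()] objects over the same cells.
#' @param labels optional [label_set()] (required for `features = "de"`).
#' @param qc optional QC tibble (`cell_id`, `nucleosome_signal`,
#'   `tss_enrichment`); when given, failing cells are dropped from both
#'   modalities and the returned `keep` mask reports survivors.
#' @param train_idx integer indices of training cells (post-QC numbering)
#'   for differential selection.
#' @param features `"reduced"` or `"de"`.
#' @param n_hvg highly variable genes to keep (capped at the gene count).
#' @param n_pcs,n_lsi embedding dimensions (capped at matrix rank limits).
#' @param k_modality,k_consensus neighbor counts (defaults 20 and 15).
#' @param de_alpha BH cutoff for the `"de"` wiring.
#' @return list with `x` (feature matrix), `graph` ([cell_graph()]),
#'   `rna_embed`, `atac_embed`, `weights` (wnn tibble), `keep` (logical
#'   mask over input cells), and `selection` (list of feature selections,
#'   `"de"` wiring only).
#' @export
preprocess_multiome <- function(rna, atac, labels = NULL, qc = NULL,
                                train_idx = NULL,
                                features = c("reduced", "de"),
                                n_hvg = 2000, n_pcs = 30, n_lsi = 20,
                                k_modality = 20, k_consensus = 15,
                                de_alpha = 0.05) {
  features <- match.arg(features)
  keep <- rep(TRUE, nrow(rna$values))
  if (!is.null(qc)) {
    keep <- qc_filter_atac(qc)
    rna <- subset_omics(rna, cells = keep)
    atac <- subset_omics(atac, cells = keep)
    if (!is.null(labels)) labels <- labels[keep, , drop = FALSE]
  }
  ## RNA branch
  rna_norm <- normalize_rna(rna)
  hvg <- select_hvg(rna_norm, min(n_hvg, ncol(rna_norm$values)))
  rna_hvg <- scale_features(subset_omics(rna_norm, features = hvg$selected_ids))
  rna_embed <- pca_reduce(rna_hvg, min(n_pcs, dim(rna_hvg$values) - 1))
  ## ATAC branch
  tfidf <- tfidf_transform(atac)
  atac_embed <- lsi_reduce(tfidf, min(n_lsi, min(dim(tfidf$values))))
  ## graph
  weights <- wnn_weights(rna_embed, atac_embed, k = k_modality)
  graph <- wnn_consensus_graph(rna_embed, atac_embed, weights,
                               k = k_consensus)
  selection <- NULL
  if (features == "reduced") {
    x <- cbind(scale(rna_embed), scale(atac_embed))
    x[!is.finite(x)] <- 0
    colnames(x) <- c(paste0("rna_pc", seq_len(ncol(rna_embed))),
                     paste0("atac_lsi", seq_len(ncol(atac_embed))))
  } else {
    if (is.null(labels) || is.null(train_idx)) {
      stop_hamgcn("features = 'de' requires labels and train_idx")
    }
    de_rna <- wilcoxon_de(rna_norm, labels$disease_state, train_idx,
                          alpha = de_alpha)
    da_atac <- wilcoxon_de(tfidf, labels$disease_state, train_idx,
                           alpha = de_alpha)
    selection <- list(rna = de_rna, atac = da_atac)
    parts <- list()
    if (length(de_rna$selected_ids) > 0) {
      parts$rna <- scale_features(
        subset_omics(rna_norm, features = de_rna$selected_ids))$values
    }
    if (length(da_atac$selected_ids) > 0) {
      parts$atac <- scale_features(
        subset_omics(tfidf, features = da_atac$selected_ids))$values
    }
    if (length(parts) == 0) stop_hamgcn("no features passed differential selection")
    x <- do.call(cbind, unname(parts))
  }
  rownames(x) <- rna$cell_ids
  list(x = x, graph = graph, rna_embed = rna_embed, atac_embed = atac_embed,
       weights = weights, keep = keep, labels = labels,
       selection = selection)
}

#' End-to-end pipeline on a (synthetic or real) multiome
#'
#' Generate-or-take a multiome, preprocess, build the graph, split, fit, and
#' evaluate. Convenience wrapper used by the command-line interface, the
#' examples and the acceptance analyses.
#'
#' @param data list with `rna`, `atac`, `labels` and optionally `qc` (as
#'   produced by [make_multiome()]).
#' @param config a [model_config()].
#' @param mode `"hgcn"` or `"gcn_baseline"`.
#' @param split_mode `"cell_level"` or `"donor_grouped"`.
#' @param fractions train/val/test fractions.
#' @param use_qc apply the ATAC QC filter before anything else.
#' @param features classifier feature wiring, see [preprocess_multiome()].
#' @return list with `fit` (a `hamgcn_fit`), `prep` (the preprocessing
#'   bundle), `split`, and `metrics` (test-set [evaluate_fit()] output).
#' @export
run_pipeline <- function(data, config = model_config(),
                         mode = c("hgcn", "gcn_baseline"),
                         split_mode = "cell_level",
                         fractions = c(0.6, 0.2, 0.2), use_qc = FALSE,
                         features = "reduced") {
  mode <- match.arg(mode)
  qc <- if (use_qc) data$qc else NULL
  labels <- data$labels
  if (use_qc && !is.null(qc)) {
    ## split after QC so indices refer to surviving cells
  }
  prep0 <- if (features == "de") {
    keep <- if (use_qc) qc_filter_atac(qc) else rep(TRUE, nrow(data$labels))
    lab_kept <- data$labels[keep, , drop = FALSE]
    split <- split_cells(lab_kept, fractions, mode = split_mode,
                         seed = config$seed)
    preprocess_multiome(data$rna, data$atac, labels = data$labels, qc = qc,
                        train_idx = split$train, features = "de")
  } else {
    preprocess_multiome(data$rna, data$atac, labels = data$labels, qc = qc,
                        features = "reduced")
  }
  labels <- prep0$labels %||% data$labels
  if (features != "de") {
    split <- split_cells(labels, fractions, mode = split_mode,
                         seed = config$seed)
  }
  fit <- fit_hamgcn(prep0$x, prep0$graph, labels, split, config, mode = mode)
  metrics <- evaluate_fit(fit, "test")
  list(fit = fit, prep = prep0, split = split, metrics = metrics)
}
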