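#' Energy drift statistics from recorded traces
#'
#' Each epoch's trace is the energy evaluated at the initial state and after
#' every integrator step. The per-epoch drift is
#' `100 * |H_last - H_first| / max(|H_first|, eps)`; the summary is its mean
#' and standard deviation over epochs. Drift is invariant to rescaling all
#' energies by a positive constant.
#'
#' @param traces list of numeric per-step energy vectors (one per epoch),
#'   e.g. `fit$energy_traces`, or a single numeric vector.
#' @param eps floor for the relative denominator.
#' @return tibble with `mean_drift_percent`, `sd_drift_percent`, `n_epochs`.
#' @export
energy_drift <- function(traces, eps = 1e-12) {
  if (is.numeric(traces)) traces <- list(traces)
  traces <- traces[!vapply(traces, is.null, logical(1))]
  if (length(traces) == 0) stop_hamgcn("empty energy trace")
  drifts <- vapply(traces, function(tr) {
    if (length(tr) < 2) stop_hamgcn("trace needs at least two energies")
    100 * abs(tr[length(tr)] - tr[1]) / max(abs(tr[1]), eps)
  }, numeric(1))
  tibble::tibble(mean_drift_percent = mean(drifts),
                 sd_drift_percent = if (length(drifts) > 1) sd(drifts) else 0,
                 n_epochs = length(drifts))
}

## subsample pair indices (i, j), i < j, uniformly without replacement
sample_pairs <- function(n, max_pairs, seed) {
  total <- n * (n - 1) / 2
  if (total <= max_pairs) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    return(cbind(idx[, 1], idx[, 2]))
  }
  set.seed(derive_seed(seed, "diagnose"))
  keys <- sample(total, max_pairs)
  ## map linear upper-triangle key (column-major) to (i, j)
  j <- ceiling((1 + sqrt(1 + 8 * keys)) / 2)
  i <- keys - (j - 1) * (j - 2) / 2
  cbind(i, j)
}

#' Mean pairwise cosine similarity of embeddings
#'
#' Over all unordered pairs when feasible, else over `max_pairs` uniformly
#' sampled pairs (seeded). Zero rows contribute similarity 0.
#'
#' @param embeddings N x d matrix.
#' @param max_pairs pair-count cap for the O(N^2) computation.
#' @param seed sampling seed.
#' @return scalar in `[-1, 1]`.
#' @export
mean_pairwise_cosine <- function(embeddings, max_pairs = 1e5, seed = 1) {
  x <- as.matrix(embeddings)
  if (nrow(x) < 2) stop_hamgcn("need at least two rows")
  pr <- sample_pairs(nrow(x), max_pairs, seed)
  mean(row_cosine(x[pr[, 1], , drop = FALSE], x[pr[, 2], , drop = FALSE]))
}

#' Dirichlet energy of embeddings on a graph
#'
#' The unnormalized form: the sum over edges of the squared Euclidean
#' distance between endpoint embeddings. Low values indicate smooth —
#' potentially collapsed — embeddings.
#'
#' @param embeddings N x d matrix.
#' @param graph a [cell_graph()] with N nodes.
#' @return non-negative scalar.
#' @export
dirichlet_energy <- function(embeddings, graph) {
  x <- as.matrix(embeddings)
  if (nrow(x) != graph$n_nodes) stop_hamgcn("embedding/graph size mismatch")
  e <- graph$edges
  if (nrow(e) == 0) return(0)
  d <- x[e[, 1] + 1L, , drop = FALSE] - x[e[, 2] + 1L, , drop = FALSE]
  sum(d * d)
}

#' Intra/inter-class cosine similarity and smoothness ratio
#'
#' Mean cosine similarity over same-class pairs (intra) and cross-class
#' pairs (inter), both subsampled with the same cap as
#' [mean_pairwise_cosine()]; the smoothness ratio is `inter / intra`. A
#' ratio near 1 means classes are as similar to each other as to
#' themselves — the over-smoothed regime.
#'
#' @param embeddings N x d matrix.
#' @param labels per-row class labels (at least 2 classes).
#' @param max_pairs pair cap.
#' @param seed sampling seed.
#' @return tibble with `intra`, `inter`, `ratio`.
#' @export
class_similarity <- function(embeddings, labels, max_pairs = 1e5, seed = 1) {
  x <- as.matrix(embeddings)
  lab <- as.factor(labels)
  if (nlevels(droplevels(lab)) < 2) stop_hamgcn("need at least two classes")
  if (any(table(lab) == 1)) {
    warning("class(es) of size 1 contribute no intra-class pairs")
  }
  pr <- sample_pairs(nrow(x), max_pairs, seed)
  sims <- row_cosine(x[pr[, 1], , drop = FALSE], x[pr[, 2], , drop = FALSE])
  same <- lab[pr[, 1]] == lab[pr[, 2]]
  intra <- mean(sims[same])
  inter <- mean(sims[!same])
  tibble::tibble(intra = intra, inter = inter,
                 ratio = if (intra != 0) inter / intra else NA_real_)
}

#' Two-component PCA of the phase state
#'
#' PCA on the concatenated `(q || p)` matrix: top-2 scores and the
#' explained-variance fractions of the leading components, with the same
#' deterministic sign convention as [pca_reduce()].
#'
#' @param state a [phase_state()] (or plain matrix).
#' @param n_components how many explained-variance fractions to report.
#' @return list with `coords` (N x 2 score matrix) and
#'   `explained_variance_fractions`.
#' @export
phase_pca <- function(state, n_components = 2) {
  x <- if (inherits(state, "phase_state")) cbind(state$q, state$p)
       else as.matrix(state)
  if (nrow(x) < 2) stop_hamgcn("need at least two rows")
  xc <- sweep(x, 2L, colMeans(x), "-")
  sv <- svd(xc)
  k <- min(n_components, length(sv$d))
  scores <- fix_svd_signs(sv, max(2L, k), rownames(x))
  total <- sum(sv$d^2)
  fr <- if (total > 0) sv$d[seq_len(k)]^2 / total else rep(0, k)
  list(coords = scores[, 1:2, drop = FALSE],
       explained_variance_fractions = fr)
}

#' Over-smoothing report for one embedding
#'
#' Bundles the scalar diagnostics: global mean pairwise cosine,
#' within-class mean cosine, Dirichlet energy, and the intra/inter class
#' similarity decomposition.
#'
#' @param embeddings N x d matrix.
#' @param graph a [cell_graph()].
#' @param labels per-row class labels.
#' @param max_pairs pair cap for cosine estimates.
#' @param seed sampling seed.
#' @return one-row tibble.
#' @export
smoothing_report <- function(embeddings, graph, labels, max_pairs = 1e5,
                             seed = 1) {
  cs <- class_similarity(embeddings, labels, max_pairs, seed)
  tibble::tibble(
    mean_pairwise_cosine = mean_pairwise_cosine(embeddings, max_pairs, seed),
    within_class_cosine = cs$intra,
    dirichlet_energy = dirichlet_energy(embeddings, graph),
    intra_class_sim = cs$intra, inter_class_sim = cs$inter,
    smoothness_ratio = cs$ratio
  )
}

#' Depth / integration-horizon sweep
#'
#' Trains the GCN baseline across a grid of depths and the Hamiltonian model
#' across a grid of integration horizons (matched "depths"), then reports
#' test accuracy and over-smoothing diagnostics per setting in tidy form —
#' the desk-scale analogue of the depth-ablation analysis.
#'
#' @param x,graph,labels,split as in [fit_hamgcn()].
#' @param config base [model_config()].
#' @param gcn_depths integer vector of baseline depths.
#' @param hgcn_horizons numeric vector of horizon end-points (start 0).
#' @param seeds integer vector of seeds.
#' @return tibble: model, depth_or_horizon, seed, test accuracy, f1_macro,
#'   and the smoothing diagnostics.
#' @export
depth_sweep <- function(x, graph, labels, split, config = model_config(),
                        gcn_depths = c(1, 2, 4, 8),
                        hgcn_horizons = c(1, 2, 4), seeds = 1) {
  runs <- list()
  lab_vec <- if (is.atomic(labels) || is.factor(labels)) labels
             else labels$composite
  run_one <- function(mode, val, seed) {
    cfg <- config
    cfg$seed <- seed
    if (mode == "gcn_baseline") cfg$depth <- val else cfg$horizon <- c(0, val)
    fit <- fit_hamgcn(x, graph, labels, split, cfg, mode = mode)
    ev <- evaluate_fit(fit, "test")
    emb <- model_embedding(fit)
    sm <- smoothing_report(emb, graph, lab_vec, seed = seed)
    dplyr::bind_cols(
      tibble::tibble(model = mode, depth_or_horizon = val, seed = seed,
                     accuracy = ev$summary$accuracy,
                     f1_macro = ev$summary$f1_macro),
      sm)
  }
  for (seed in seeds) {
    for (d in gcn_depths) runs[[length(runs) + 1L]] <- run_one("gcn_baseline", d, seed)
    for (tt in hgcn_horizons) runs[[length(runs) + 1L]] <- run_one("hgcn", tt, seed)
  }
  dplyr::bind_rows(runs)
}
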