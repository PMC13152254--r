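#' Perturbation settings
#'
#' @param feature_fraction fraction of nodes whose features are corrupted.
#' @param feature_mode `"bitflip"` (binary entries toggled, continuous
#'   entries sign-flipped; `"zero"` available via `bitflip_zero`) or
#'   `"shift"` (additive Gaussian noise scaled per feature).
#' @param shift_sigma noise scale in units of per-feature standard
#'   deviations (default 1).
#' @param bitflip_zero if `TRUE`, continuous "bit-flips" set entries to zero
#'   instead of negating.
#' @param edge_remove_fraction,edge_add_fraction fractions of existing edges
#'   removed / added (added edges are sampled from non-edges).
#' @param seed mandatory integer seed.
#' @return a `perturbation_spec` list.
#' @export
perturbation_spec <- function(feature_fraction = 0,
                              feature_mode = c("bitflip", "shift"),
                              shift_sigma = 1, bitflip_zero = FALSE,
                              edge_remove_fraction = 0,
                              edge_add_fraction = 0, seed) {
  feature_mode <- match.arg(feature_mode)
  if (missing(seed)) stop_hamgcn("perturbation seed is mandatory")
  fr <- c(feature_fraction, edge_remove_fraction, edge_add_fraction)
  if (any(fr < 0 | fr > 1)) stop_hamgcn("fractions must lie in [0, 1]")
  structure(list(feature_fraction = feature_fraction,
                 feature_mode = feature_mode, shift_sigma = shift_sigma,
                 bitflip_zero = bitflip_zero,
                 edge_remove_fraction = edge_remove_fraction,
                 edge_add_fraction = edge_add_fraction,
                 seed = as.integer(seed)),
            class = "perturbation_spec")
}

#' Corrupt node features
#'
#' A seeded uniform sample of `ceiling(feature_fraction * N)` nodes is
#' selected; `bitflip` toggles 0/1 entries and sign-flips (or zeroes)
#' continuous entries of the selected rows, `shift` adds Gaussian noise with
#' standard deviation `shift_sigma` times the per-feature standard
#' deviation. Unselected rows are bit-identical to the input.
#'
#' @param x N x F numeric matrix.
#' @param spec a [perturbation_spec()].
#' @return perturbed matrix of the same shape.
#' @export
perturb_features <- function(x, spec) {
  x <- as.matrix(x)
  n_sel <- ceiling(spec$feature_fraction * nrow(x))
  if (n_sel == 0) return(x)
  set.seed(derive_seed(spec$seed, "perturb"))
  rows <- sample.int(nrow(x), n_sel)
  if (spec$feature_mode == "bitflip") {
    sub <- x[rows, , drop = FALSE]
    binary <- sub == 0 | sub == 1
    sub[binary] <- 1 - sub[binary]
    sub[!binary] <- if (spec$bitflip_zero) 0 else -sub[!binary]
    x[rows, ] <- sub
  } else {
    sds <- apply(x, 2L, sd)
    noise <- matrix(rnorm(n_sel * ncol(x)), n_sel, ncol(x))
    x[rows, ] <- x[rows, , drop = FALSE] +
      sweep(noise, 2L, spec$shift_sigma * sds, "*")
  }
  x
}

#' Corrupt graph structure
#'
#' Removes a seeded uniform sample of `ceiling(edge_remove_fraction * |E|)`
#' existing edges and adds `ceiling(edge_add_fraction * |E|)` uniformly
#' sampled non-edges (never self-loops or duplicates). The result satisfies
#' all cell-graph invariants; `|E'| = |E| - removed + added` exactly.
#'
#' @param graph a [cell_graph()].
#' @param spec a [perturbation_spec()].
#' @return a perturbed [cell_graph()].
#' @export
perturb_edges <- function(graph, spec) {
  e <- graph$edges
  m <- nrow(e)
  n <- graph$n_nodes
  n_rm <- ceiling(spec$edge_remove_fraction * m)
  n_add <- ceiling(spec$edge_add_fraction * m)
  total_pairs <- n * (n - 1) / 2
  if (n_add > total_pairs - (m - n_rm)) {
    stop_hamgcn("not enough non-edges available to add")
  }
  set.seed(derive_seed(spec$seed, "perturb") + 1L)
  keep <- e
  if (n_rm > 0) keep <- e[-sample.int(m, n_rm), , drop = FALSE]
  if (n_add > 0) {
    key <- function(a, b) a * n + b    # a < b, unique per pair
    existing <- key(keep[, 1], keep[, 2])
    new_edges <- matrix(integer(), 0, 2)
    while (nrow(new_edges) < n_add) {
      need <- n_add - nrow(new_edges)
      a <- sample.int(n, 2 * need + 10, replace = TRUE) - 1L
      b <- sample.int(n, 2 * need + 10, replace = TRUE) - 1L
      lo <- pmin(a, b); hi <- pmax(a, b)
      ok <- lo < hi
      cand <- cbind(lo[ok], hi[ok])
      cand <- cand[!duplicated(key(cand[, 1], cand[, 2])), , drop = FALSE]
      cand <- cand[!(key(cand[, 1], cand[, 2]) %in%
                       c(existing, key(new_edges[, 1], new_edges[, 2]))), ,
                   drop = FALSE]
      if (nrow(cand) > need) cand <- cand[seq_len(need), , drop = FALSE]
      new_edges <- rbind(new_edges, cand)
    }
    keep <- rbind(keep, new_edges)
  }
  cell_graph(n, keep)
}

#' Robustness sweep over perturbation intensities
#'
#' For each intensity and seed, features and edges are corrupted at that
#' fraction (features via the chosen mode; edges by removing and adding the
#' same fraction — the combined protocol), both models are trained on the
#' corrupted data under identical seeds and splits (perturb-then-train), and
#' test accuracy/F1 are recorded in tidy form. Intensity 0 rows equal the
#' unperturbed evaluation exactly.
#'
#' @param x,graph,labels,split as in [fit_hamgcn()].
#' @param config base [model_config()].
#' @param intensities numeric corruption fractions
#'   (default `c(0, 0.05, 0.10, 0.15, 0.20, 0.25, 0.30)`).
#' @param seeds integer vector of seeds.
#' @param modes models to run.
#' @param feature_mode passed to [perturbation_spec()].
#' @param perturb_features_flag,perturb_edges_flag independent overrides to
#'   corrupt only one surface.
#' @return tibble: model, intensity, seed, split, accuracy, f1_macro.
#' @export
robustness_sweep <- function(x, graph, labels, split,
                             config = model_config(),
                             intensities = c(0, 0.05, 0.10, 0.15, 0.20,
                                             0.25, 0.30),
                             seeds = 1:5,
                             modes = c("hgcn", "gcn_baseline"),
                             feature_mode = "shift",
                             perturb_features_flag = TRUE,
                             perturb_edges_flag = TRUE) {
  out <- list()
  for (intensity in intensities) {
    for (seed in seeds) {
      spec <- perturbation_spec(
        feature_fraction = if (perturb_features_flag) intensity else 0,
        feature_mode = feature_mode,
        edge_remove_fraction = if (perturb_edges_flag) intensity else 0,
        edge_add_fraction = if (perturb_edges_flag) intensity else 0,
        seed = seed)
      xp <- perturb_features(x, spec)
      gp <- perturb_edges(graph, spec)
      for (mode in modes) {
        cfg <- config
        cfg$seed <- seed
        fit <- fit_hamgcn(xp, gp, labels, split, cfg, mode = mode)
        ev <- evaluate_fit(fit, "test")
        out[[length(out) + 1L]] <- tibble::tibble(
          model = mode, intensity = intensity, seed = seed, split = "test",
          accuracy = ev$summary$accuracy, f1_macro = ev$summary$f1_macro)
      }
    }
  }
  dplyr::bind_rows(out)
}
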