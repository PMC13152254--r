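#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_hline labs
#'   facet_wrap theme_minimal autoplot scale_color_brewer
NULL

#' Plot the training history of a fitted model
#'
#' Train/validation loss and validation accuracy per epoch.
#'
#' @param object a `hamgcn_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.hamgcn_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history,
                              c("train_loss", "val_loss", "val_accuracy"),
                              names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$epoch, y = .data$value,
                   color = .data$metric)) +
    geom_line() +
    facet_wrap(~metric, scales = "free_y", ncol = 1) +
    labs(x = "epoch", y = NULL,
         title = sprintf("Training history (%s)", object$mode)) +
    theme_minimal()
}

#' Plot per-step energy traces across epochs
#'
#' One line per (sampled) epoch showing the learned Hamiltonian evaluated at
#' the initial state and after each symplectic step; flat lines indicate
#' approximate energy conservation, bounded wiggle is expected from
#' discretization.
#'
#' @param fit a `hamgcn_fit` trained in `"hgcn"` mode.
#' @param max_epochs at most this many epochs are drawn (evenly spaced).
#' @return a ggplot object.
#' @export
plot_energy_traces <- function(fit, max_epochs = 20) {
  traces <- fit$energy_traces
  traces <- traces[!vapply(traces, is.null, logical(1))]
  if (length(traces) == 0) stop_hamgcn("fit has no recorded energy traces")
  keep <- unique(round(seq(1, length(traces), length.out = min(max_epochs,
                                                               length(traces)))))
  df <- purrr::map_dfr(keep, function(ep) {
    tibble::tibble(epoch = ep, step = seq_along(traces[[ep]]) - 1L,
                   energy = traces[[ep]])
  })
  ggplot(df, aes(x = .data$step, y = .data$energy, group = .data$epoch,
                 color = .data$epoch)) +
    geom_line(alpha = 0.7) +
    labs(x = "integration step", y = "energy H(q, p)",
         title = "Energy traces across training epochs") +
    theme_minimal()
}

#' Plot a robustness sweep
#'
#' Mean test accuracy (over seeds) against perturbation intensity, one line
#' per model.
#'
#' @param sweep tibble from [robustness_sweep()].
#' @return a ggplot object.
#' @export
plot_robustness <- function(sweep) {
  agg <- dplyr::summarise(
    dplyr::group_by(sweep, .data$model, .data$intensity),
    accuracy = mean(.data$accuracy), .groups = "drop")
  ggplot(agg, aes(x = .data$intensity, y = .data$accuracy,
                  color = .data$model)) +
    geom_line() + geom_point() +
    labs(x = "perturbation intensity", y = "mean test accuracy",
         title = "Robustness under combined feature-edge perturbation") +
    theme_minimal()
}

#' Plot a depth / horizon sweep
#'
#' Accuracy and mean pairwise cosine similarity against effective depth
#' (layers for the baseline, integration horizon for the Hamiltonian
#' model) — the over-smoothing picture.
#'
#' @param sweep tibble from [depth_sweep()].
#' @return a ggplot object.
#' @export
plot_depth_sweep <- function(sweep) {
  long <- tidyr::pivot_longer(sweep, c("accuracy", "mean_pairwise_cosine"),
                              names_to = "metric", values_to = "value")
  agg <- dplyr::summarise(
    dplyr::group_by(long, .data$model, .data$depth_or_horizon, .data$metric),
    value = mean(.data$value), .groups = "drop")
  ggplot(agg, aes(x = .data$depth_or_horizon, y = .data$value,
                  color = .data$model)) +
    geom_line() + geom_point() +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "depth (GCN) / horizon (HGCN)", y = NULL,
         title = "Over-smoothing across depth") +
    theme_minimal()
}

#' Plot the two leading principal components of a phase state
#'
#' @param state a [phase_state()] (or matrix).
#' @param labels optional point labels (colors).
#' @return a ggplot object.
#' @export
plot_phase_pca <- function(state, labels = NULL) {
  pc <- phase_pca(state)
  df <- tibble::tibble(pc1 = pc$coords[, 1], pc2 = pc$coords[, 2],
                       label = if (is.null(labels)) "all"
                               else as.character(labels))
  ggplot(df, aes(x = .data$pc1, y = .data$pc2, color = .data$label)) +
    geom_point(size = 0.8, alpha = 0.8) +
    labs(x = sprintf("PC1 (%.1f%%)",
                     100 * pc$explained_variance_fractions[1]),
         y = sprintf("PC2 (%.1f%%)",
                     100 * pc$explained_variance_fractions[2]),
         title = "Phase-space principal components") +
    theme_minimal()
}
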