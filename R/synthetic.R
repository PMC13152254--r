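#' Synthetic multiome generator settings
#'
#' Defaults emulate the structure of a paired RNA + ATAC disease atlas at
#' desk scale: 2,000 cells in 8 cell types x 2 disease states (16 balanced
#' composite classes), 8 donors (4 per state), negative-binomial RNA counts
#' with strong type markers and moderate disease effects, zero-inflated
#' Poisson ATAC counts, multiplicative dropout, and additive donor shifts.
#' Effect sizes are fixed generator conditions, not tuning knobs: cell-type
#' markers at |log-FC| 2.5 on 30% of features (cell identity programs are
#' strong and nearly saturating, as in real atlases), disease effects at
#' |log-FC| 1.2 on a disjoint 10% (disease signatures are real but
#' subtler), donor shifts s.d. 0.15, RNA dispersion 0.3, ATAC
#' zero-inflation 0.5, dropout 0.2.
#'
#' @param n_cells total cells.
#' @param n_types,n_states class structure (composite = types x states).
#' @param n_donors donors, split evenly across states.
#' @param rna_dim,atac_dim feature counts per modality.
#' @param type_de_fraction fraction of features carrying cell-type effects.
#' @param state_de_fraction disjoint fraction carrying disease-state effects.
#' @param type_lfc,state_lfc absolute log-fold-change of the effects.
#' @param rna_dispersion negative-binomial dispersion (1/size).
#' @param atac_sparsity zero-inflation probability for ATAC counts.
#' @param donor_sd s.d. of additive per-donor log-shifts.
#' @param dropout_rate probability an RNA count is zeroed (dropout).
#' @param seed mandatory integer seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_cells = 2000, n_types = 8, n_states = 2,
                           n_donors = 8, rna_dim = 300, atac_dim = 400,
                           type_de_fraction = 0.3, state_de_fraction = 0.1,
                           type_lfc = 2.5, state_lfc = 1.2,
                           rna_dispersion = 0.3, atac_sparsity = 0.5,
                           donor_sd = 0.15, dropout_rate = 0.2, seed) {
  if (missing(seed)) stop_hamgcn("generator seed is mandatory")
  stopifnot(n_cells > 0, rna_dim > 0, atac_dim > 0)
  fr <- c(type_de_fraction, state_de_fraction, atac_sparsity, dropout_rate)
  if (any(fr < 0 | fr > 1)) stop_hamgcn("fractions must lie in [0, 1]")
  structure(as.list(environment()), class = "synthetic_spec")
}

## effect map: which features carry which factor's effect, with signed lfc
plant_effects <- function(n_feat, n_classes, fraction, lfc, prefix) {
  n_de <- round(fraction * n_feat)
  idx <- seq_len(n_de)                      # leading block; disjointness is
  cls <- rep_len(seq_len(n_classes), n_de)  # handled by the caller's offset
  sign <- rep_len(c(1, -1), n_de)
  tibble::tibble(feature = idx, class = cls, lfc = sign * lfc)
}

#' Generate a paired RNA + ATAC synthetic multiome
#'
#' Draws a balanced composite class (cell type x disease state) per cell,
#' assigns donors within disease state, and samples RNA counts from a
#' negative binomial with class-specific log-means (type effects on one
#' block of genes, state effects on a disjoint block, additive donor
#' shifts, multiplicative dropout) and ATAC counts from a zero-inflated
#' Poisson with class-specific accessibility. QC metrics are sampled so a
#' few percent of cells fail the standard ATAC thresholds. Ground-truth
#' effect tables are returned so differential-selection operators can be
#' validated against the planted features. Bit-identical for a fixed seed.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `rna`, `atac` ([omics_matrix()]s), `labels`
#'   ([label_set()]), `qc` (tibble: cell_id, nucleosome_signal,
#'   tss_enrichment), and `truth` (tibble: modality, feature_id, factor,
#'   class, lfc).
#' @export
make_multiome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(derive_seed(spec$seed, "simulate"))
  n <- spec$n_cells
  n_comp <- spec$n_types * spec$n_states
  comp <- rep_len(seq_len(n_comp), n)        # balanced within 1 cell
  comp <- comp[sample.int(n)]
  type <- ((comp - 1L) %/% spec$n_states) + 1L
  state <- ((comp - 1L) %% spec$n_states) + 1L
  donors_per_state <- max(1L, spec$n_donors %/% spec$n_states)
  donor <- integer(n)
  for (s in seq_len(spec$n_states)) {
    idx <- which(state == s)
    donor[idx] <- (s - 1L) * donors_per_state +
      rep_len(seq_len(donors_per_state), length(idx))
  }
  ## ---- RNA ----
  g <- spec$rna_dim
  base <- rnorm(g, log(3), 1)
  type_fx <- plant_effects(g, spec$n_types, spec$type_de_fraction,
                           spec$type_lfc, "rna")
  off <- round(spec$type_de_fraction * g)
  state_fx <- plant_effects(g - off, spec$n_states, spec$state_de_fraction *
                              g / (g - off), spec$state_lfc, "rna")
  state_fx$feature <- state_fx$feature + off
  donor_shift <- matrix(rnorm(spec$n_donors * g, 0, spec$donor_sd),
                        spec$n_donors, g)
  lib <- exp(rnorm(n, 0, 0.3))
  logmu <- matrix(base, n, g, byrow = TRUE)
  for (r in seq_len(nrow(type_fx))) {
    logmu[type == type_fx$class[r], type_fx$feature[r]] <-
      logmu[type == type_fx$class[r], type_fx$feature[r]] + type_fx$lfc[r]
  }
  for (r in seq_len(nrow(state_fx))) {
    logmu[state == state_fx$class[r], state_fx$feature[r]] <-
      logmu[state == state_fx$class[r], state_fx$feature[r]] + state_fx$lfc[r]
  }
  logmu <- logmu + donor_shift[donor, , drop = FALSE]
  mu <- exp(logmu) * lib
  rna <- matrix(rnbinom(n * g, size = 1 / spec$rna_dispersion, mu = mu), n, g)
  if (spec$dropout_rate > 0) {
    drop <- matrix(runif(n * g) < spec$dropout_rate, n, g)
    rna[drop] <- 0L
  }
  rna_ids <- sprintf("gene_%03d", seq_len(g))
  ## ---- ATAC ----
  pk <- spec$atac_dim
  base_a <- rnorm(pk, log(1.2), 0.8)
  type_fa <- plant_effects(pk, spec$n_types, spec$type_de_fraction,
                           spec$type_lfc, "atac")
  offa <- round(spec$type_de_fraction * pk)
  state_fa <- plant_effects(pk - offa, spec$n_states, spec$state_de_fraction *
                              pk / (pk - offa), spec$state_lfc, "atac")
  state_fa$feature <- state_fa$feature + offa
  logla <- matrix(base_a, n, pk, byrow = TRUE)
  for (r in seq_len(nrow(type_fa))) {
    logla[type == type_fa$class[r], type_fa$feature[r]] <-
      logla[type == type_fa$class[r], type_fa$feature[r]] + type_fa$lfc[r]
  }
  for (r in seq_len(nrow(state_fa))) {
    logla[state == state_fa$class[r], state_fa$feature[r]] <-
      logla[state == state_fa$class[r], state_fa$feature[r]] + state_fa$lfc[r]
  }
  atac <- matrix(rpois(n * pk, exp(logla)), n, pk)
  zi <- matrix(runif(n * pk) < spec$atac_sparsity, n, pk)
  atac[zi] <- 0L
  atac_ids <- sprintf("peak_%03d", seq_len(pk))
  cell_ids <- sprintf("cell_%04d", seq_len(n))
  ## ---- QC metrics: ~5% of cells fail the standard thresholds ----
  qc <- tibble::tibble(
    cell_id = cell_ids,
    nucleosome_signal = abs(rnorm(n, 1.2, 0.4)),
    tss_enrichment = rnorm(n, 4, 1)
  )
  labels <- label_set(
    cell_type = paste0("type", type),
    disease_state = c("control", "disease")[state],
    donor_id = paste0("donor", donor), cell_id = cell_ids)
  truth <- dplyr::bind_rows(
    dplyr::mutate(type_fx, modality = "rna", factor = "cell_type",
                  feature_id = rna_ids[.data$feature]),
    dplyr::mutate(state_fx, modality = "rna", factor = "disease_state",
                  feature_id = rna_ids[.data$feature]),
    dplyr::mutate(type_fa, modality = "atac", factor = "cell_type",
                  feature_id = atac_ids[.data$feature]),
    dplyr::mutate(state_fa, modality = "atac", factor = "disease_state",
                  feature_id = atac_ids[.data$feature])
  )[, c("modality", "feature_id", "factor", "class", "lfc")]
  list(
    rna = omics_matrix(rna, cell_ids, rna_ids, modality = "rna"),
    atac = omics_matrix(atac, cell_ids, atac_ids, modality = "atac"),
    labels = labels, qc = qc, truth = truth
  )
}

#' Stochastic block model graph with Gaussian class features
#'
#' Edges within a block appear with probability `p_in`, across blocks with
#' `p_out < p_in`; node features are the block mean (Gaussian, scaled by
#' `mean_scale`) plus unit Gaussian noise. Test bed for over-smoothing and
#' perturbation analyses.
#'
#' @param n nodes.
#' @param blocks number of blocks (balanced).
#' @param p_in,p_out edge probabilities (`p_in > p_out`).
#' @param feature_dim feature dimensionality.
#' @param seed mandatory seed.
#' @param mean_scale separation of class means (default 1).
#' @return list with `graph` ([cell_graph()]), `x` (n x feature_dim matrix),
#'   `labels` (factor of block memberships).
#' @export
make_sbm_graph <- function(n, blocks, p_in, p_out, feature_dim, seed,
                           mean_scale = 1) {
  if (p_in <= p_out) stop_hamgcn("p_in must exceed p_out")
  set.seed(derive_seed(seed, "simulate") + 7L)
  lab <- rep_len(seq_len(blocks), n)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  same <- lab[pairs[, 1]] == lab[pairs[, 2]]
  prob <- ifelse(same, p_in, p_out)
  keep <- runif(nrow(pairs)) < prob
  graph <- cell_graph(n, cbind(pairs[keep, 1], pairs[keep, 2]) - 1L)
  means <- matrix(rnorm(blocks * feature_dim), blocks, feature_dim) * mean_scale
  x <- means[lab, , drop = FALSE] +
    matrix(rnorm(n * feature_dim), n, feature_dim)
  list(graph = graph, x = x, labels = factor(paste0("block", lab)))
}
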