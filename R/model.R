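#' Model hyperparameter configuration
#'
#' Defaults follow the reference configuration: hidden dimension 256 (phase
#' dimension 512), symplectic step 0.2 over horizon `[0, 1]` (5 steps),
#' dropout 0.5 applied after the encoder GCN layer, Adam with learning rate
#' 0.01 and weight decay 5e-4, early-stopping patience 50, consensus-graph
#' k = 15, and multi-task weights `alpha = 0.7` (cell type), `beta = 0.3`
#' (disease state). Desk-scale analyses typically shrink `hidden_dim` and
#' `epochs`; everything else carries over unchanged.
#'
#' @param hidden_dim H, width of each of q and p.
#' @param dt integration step size.
#' @param horizon numeric length-2 integration interval.
#' @param dropout dropout rate after the encoder GCN layer.
#' @param learning_rate,weight_decay Adam settings.
#' @param epochs maximum epochs.
#' @param patience early-stopping patience (epochs without val improvement).
#' @param k consensus-graph neighbor count (recorded for provenance).
#' @param alpha,beta multi-task loss weights; must sum to 1.
#' @param task `"single"` (one composite head) or `"multi"` (cell-type +
#'   disease-state heads combined with `alpha`/`beta`).
#' @param head_input `"qp"` (readout on the concatenated phase state,
#'   default) or `"q"` (positions only, for ablation).
#' @param variant Hamiltonian variant used in training (`"mlp"`).
#' @param depth GCN-baseline depth (ignored by the hgcn mode); default 2,
#'   the standard two-layer GCN.
#' @param seed global seed; fans out per stage via [derive_seed()].
#' @return a `model_config` list.
#' @export
model_config <- function(hidden_dim = 256, dt = 0.2, horizon = c(0, 1),
                         dropout = 0.5, learning_rate = 0.01,
                         weight_decay = 5e-4, epochs = 300, patience = 50,
                         k = 15, alpha = 0.7, beta = 0.3,
                         task = c("single", "multi"),
                         head_input = c("qp", "q"), variant = "mlp",
                         depth = 2, seed = 1) {
  task <- match.arg(task)
  head_input <- match.arg(head_input)
  if (dt <= 0) stop_hamgcn("dt must be positive")
  span <- horizon[2] - horizon[1]
  if (span < 0) stop_hamgcn("horizon end must be >= start")
  if (abs(span / dt - round(span / dt)) > 1e-8) {
    stop_hamgcn("horizon length must be divisible by dt")
  }
  if (abs(alpha + beta - 1) > 1e-8) stop_hamgcn("alpha + beta must equal 1")
  structure(list(hidden_dim = hidden_dim, dt = dt, horizon = horizon,
                 dropout = dropout, learning_rate = learning_rate,
                 weight_decay = weight_decay, epochs = epochs,
                 patience = patience, k = k, alpha = alpha, beta = beta,
                 task = task, head_input = head_input, variant = variant,
                 depth = depth, seed = seed),
            class = "model_config")
}

head_dim <- function(config) {
  if (config$head_input == "qp") 2L * config$hidden_dim else config$hidden_dim
}

#' Initialize model parameters (seeded Glorot-uniform)
#' @noRd
init_params <- function(mode, n_features, config, n_classes) {
  h <- config$hidden_dim
  set.seed(derive_seed(config$seed, "init"))
  params <- list()
  if (mode == "hgcn") {
    params$w_enc <- glorot(n_features, h)
    params$w_proj <- glorot(h, 2L * h)
    params$b_proj <- numeric(2L * h)
    ## small positive biases keep the energy net off its ReLU kinks and the
    ## per-node energies away from the l2 norm's non-smooth point at zero
    params$ham_w1 <- glorot(4L * h, 2L * h)
    params$ham_b1 <- rep(0.01, 4L * h)
    params$ham_w2 <- as.numeric(glorot(4L * h, 1L))
    params$ham_b2 <- 0.1
  } else {
    dims <- c(n_features, rep(h, config$depth))
    for (l in seq_len(config$depth)) {
      params[[paste0("w_", l)]] <- glorot(dims[l], dims[l + 1])
    }
  }
  hd <- if (mode == "hgcn") head_dim(config) else h
  for (k in seq_along(n_classes)) {
    params[[paste0("head_w_", k)]] <- glorot(hd, n_classes[k])
    params[[paste0("head_b_", k)]] <- numeric(n_classes[k])
  }
  params
}

ham_spec_from_params <- function(params, h) {
  structure(list(variant = "mlp", hidden_dim = h,
                 params = list(w1 = params$ham_w1, b1 = params$ham_b1,
                               w2 = params$ham_w2, b2 = params$ham_b2)),
            class = "hamiltonian_spec")
}

#' Phase-space initialization of node embeddings
#'
#' A single GCN layer with ReLU encodes the features
#' (`Z = relu(S X W_enc)`), dropout is applied to `Z` in training mode, and a
#' linear projection maps `Z` to the 2H-dimensional phase space
#' `Y0 = Z W_proj + b`; the first H columns are the initial positions `q0`,
#' the last H the initial momenta `p0`. Evaluation mode (`training = FALSE`,
#' the default) is fully deterministic.
#'
#' @param x N x F feature matrix.
#' @param graph a [cell_graph()] (or precomputed normalized adjacency).
#' @param params list with `w_enc` (F x H), `w_proj` (H x 2H), `b_proj` (2H).
#' @param dropout dropout rate used in training mode.
#' @param training logical; apply dropout when `TRUE`.
#' @return a [phase_state()].
#' @export
phase_init <- function(x, graph, params, dropout = 0, training = FALSE) {
  s <- if (inherits(graph, "cell_graph")) normalized_adjacency(graph) else graph
  z <- relu(as.matrix(s %*% as.matrix(x) %*% params$w_enc))
  if (training && dropout > 0) {
    keep <- 1 - dropout
    m <- matrix(rbinom(length(z), 1L, keep), nrow(z), ncol(z)) / keep
    z <- z * m
  }
  y0 <- sweep(z %*% params$w_proj, 2L, params$b_proj, "+")
  h <- ncol(z %*% params$w_proj) / 2L
  phase_state(y0[, seq_len(h), drop = FALSE],
              y0[, h + seq_len(h), drop = FALSE])
}

#' Linear classification readout on the phase state
#'
#' One linear head per task, applied to the concatenated `(q || p)` per node
#' (default) or to `q` alone.
#'
#' @param state a [phase_state()].
#' @param head_params list with `w` (D x C) and `b` (C).
#' @param head_input `"qp"` or `"q"`.
#' @return N x C logit matrix.
#' @export
readout_classify <- function(state, head_params, head_input = c("qp", "q")) {
  head_input <- match.arg(head_input)
  z <- if (head_input == "qp") cbind(state$q, state$p) else state$q
  sweep(z %*% head_params$w, 2L, head_params$b, "+")
}

## ---- Internal forward passes with caches -----------------------------------

forward_hgcn <- function(x, xs, params, config, training = FALSE,
                         record_energy = FALSE) {
  h <- config$hidden_dim
  z0 <- xs %*% params$w_enc
  zr <- relu(z0)
  mask <- NULL
  zd <- zr
  if (training && config$dropout > 0) {
    keep <- 1 - config$dropout
    mask <- matrix(rbinom(length(zr), 1L, keep), nrow(zr), ncol(zr)) / keep
    zd <- zr * mask
  }
  y0 <- sweep(zd %*% params$w_proj, 2L, params$b_proj, "+")
  q <- y0[, seq_len(h), drop = FALSE]
  p <- y0[, h + seq_len(h), drop = FALSE]
  hp <- list(w1 = params$ham_w1, b1 = params$ham_b1,
             w2 = params$ham_w2, b2 = params$ham_b2)
  n_steps <- as.integer(round((config$horizon[2] - config$horizon[1]) / config$dt))
  steps <- vector("list", n_steps)
  energies <- if (record_energy) numeric(n_steps + 1L) else NULL
  for (t in seq_len(n_steps)) {
    c1 <- mlp_energy_cache(q, p, hp)
    if (record_energy && t == 1L) energies[1L] <- c1$r
    g1 <- mlp_energy_grad(c1, hp)
    p_new <- p - config$dt * g1[, seq_len(h), drop = FALSE]
    c2 <- mlp_energy_cache(q, p_new, hp)
    g2 <- mlp_energy_grad(c2, hp)
    q_new <- q + config$dt * g2[, h + seq_len(h), drop = FALSE]
    steps[[t]] <- list(c1 = c1, c2 = c2)
    q <- q_new; p <- p_new
    if (record_energy) {
      energies[t + 1L] <- mlp_energy_cache(q, p, hp)$r
    }
  }
  ztop <- if (config$head_input == "qp") cbind(q, p) else q
  logits <- list()
  k <- 1L
  while (!is.null(params[[paste0("head_w_", k)]])) {
    logits[[k]] <- sweep(ztop %*% params[[paste0("head_w_", k)]], 2L,
                         params[[paste0("head_b_", k)]], "+")
    k <- k + 1L
  }
  list(logits = logits, q = q, p = p, z0 = z0, zr = zr, mask = mask, zd = zd,
       steps = steps, hp = hp, energies = energies, ztop = ztop)
}

backward_hgcn <- function(fw, xs, params, config, dlogits) {
  h <- config$hidden_dim
  dt <- config$dt
  grads <- list()
  ## heads
  dztop <- matrix(0, nrow(fw$ztop), ncol(fw$ztop))
  for (k in seq_along(dlogits)) {
    grads[[paste0("head_w_", k)]] <- t(fw$ztop) %*% dlogits[[k]]
    grads[[paste0("head_b_", k)]] <- colSums(dlogits[[k]])
    dztop <- dztop + dlogits[[k]] %*% t(params[[paste0("head_w_", k)]])
  }
  if (config$head_input == "qp") {
    uq <- dztop[, seq_len(h), drop = FALSE]
    up <- dztop[, h + seq_len(h), drop = FALSE]
  } else {
    uq <- dztop
    up <- matrix(0, nrow(dztop), h)
  }
  hp <- fw$hp
  gham <- list(w1 = matrix(0, nrow(hp$w1), ncol(hp$w1)),
               b1 = numeric(length(hp$b1)),
               w2 = numeric(length(hp$w2)), b2 = 0)
  zero_h <- matrix(0, nrow(uq), h)
  ## reverse through the integrator: q_t = q_{t-1} + dt * Hp(q_{t-1}, p_t),
  ## p_t = p_{t-1} - dt * Hq(q_{t-1}, p_{t-1}); VJPs of grad-H are
  ## Hessian-vector products (symmetric Hessian).
  for (t in rev(seq_along(fw$steps))) {
    st <- fw$steps[[t]]
    hv2 <- mlp_energy_hvp(st$c2, hp, cbind(zero_h, uq))
    pv2 <- mlp_energy_param_vjp(st$c2, hp, cbind(zero_h, uq))
    w <- up + dt * hv2[, h + seq_len(h), drop = FALSE]
    uq_prev <- uq + dt * hv2[, seq_len(h), drop = FALSE]
    for (nm in names(gham)) gham[[nm]] <- gham[[nm]] + dt * pv2[[nm]]
    hv1 <- mlp_energy_hvp(st$c1, hp, cbind(w, zero_h))
    pv1 <- mlp_energy_param_vjp(st$c1, hp, cbind(w, zero_h))
    uq_prev <- uq_prev - dt * hv1[, seq_len(h), drop = FALSE]
    up_prev <- w - dt * hv1[, h + seq_len(h), drop = FALSE]
    for (nm in names(gham)) gham[[nm]] <- gham[[nm]] - dt * pv1[[nm]]
    uq <- uq_prev; up <- up_prev
  }
  grads$ham_w1 <- gham$w1; grads$ham_b1 <- gham$b1
  grads$ham_w2 <- gham$w2; grads$ham_b2 <- gham$b2
  dy0 <- cbind(uq, up)
  grads$w_proj <- t(fw$zd) %*% dy0
  grads$b_proj <- colSums(dy0)
  dzd <- dy0 %*% t(params$w_proj)
  dzr <- if (is.null(fw$mask)) dzd else dzd * fw$mask
  dz0 <- dzr * (fw$z0 > 0)
  grads$w_enc <- t(xs) %*% dz0
  grads
}

forward_gcn <- function(x, s, params, config, training = FALSE) {
  depth <- config$depth
  hcur <- as.matrix(x)
  pre <- vector("list", depth)
  post <- vector("list", depth)
  masks <- vector("list", depth)
  inputs <- vector("list", depth)
  for (l in seq_len(depth)) {
    inputs[[l]] <- hcur
    a <- as.matrix(s %*% hcur %*% params[[paste0("w_", l)]])
    pre[[l]] <- a
    hcur <- relu(a)
    if (training && config$dropout > 0) {
      keep <- 1 - config$dropout
      m <- matrix(rbinom(length(hcur), 1L, keep), nrow(hcur), ncol(hcur)) / keep
      masks[[l]] <- m
      hcur <- hcur * m
    }
    post[[l]] <- hcur
  }
  logits <- list()
  k <- 1L
  while (!is.null(params[[paste0("head_w_", k)]])) {
    logits[[k]] <- sweep(hcur %*% params[[paste0("head_w_", k)]], 2L,
                         params[[paste0("head_b_", k)]], "+")
    k <- k + 1L
  }
  list(logits = logits, top = hcur, pre = pre, post = post, masks = masks,
       inputs = inputs)
}

backward_gcn <- function(fw, s, params, config, dlogits) {
  grads <- list()
  dtop <- matrix(0, nrow(fw$top), ncol(fw$top))
  for (k in seq_along(dlogits)) {
    grads[[paste0("head_w_", k)]] <- t(fw$top) %*% dlogits[[k]]
    grads[[paste0("head_b_", k)]] <- colSums(dlogits[[k]])
    dtop <- dtop + dlogits[[k]] %*% t(params[[paste0("head_w_", k)]])
  }
  dh <- dtop
  for (l in rev(seq_len(config$depth))) {
    if (!is.null(fw$masks[[l]])) dh <- dh * fw$masks[[l]]
    da <- dh * (fw$pre[[l]] > 0)
    sda <- as.matrix(s %*% da)       # S symmetric
    grads[[paste0("w_", l)]] <- t(fw$inputs[[l]]) %*% sda
    dh <- sda %*% t(params[[paste0("w_", l)]])
  }
  grads
}

#' Full model forward pass (inference mode)
#'
#' Runs either the Hamiltonian model (`phase_init` -> symplectic integration
#' -> linear readout) or the plain GCN baseline (a stack of GCN layers of
#' configurable depth with the same hidden width and readout) and returns
#' logits plus the final embedding used by the over-smoothing diagnostics.
#'
#' @param x N x F feature matrix.
#' @param graph a [cell_graph()].
#' @param params parameter list (see [fit_hamgcn()] which creates it).
#' @param config a [model_config()].
#' @param mode `"hgcn"` or `"gcn_baseline"`.
#' @return list with `logits` (list of matrices, one per head) and
#'   `embedding` (N x D matrix; `(q || p)` for hgcn, last hidden layer for
#'   the baseline).
#' @export
hamgcn_forward <- function(x, graph, params, config,
                           mode = c("hgcn", "gcn_baseline")) {
  mode <- match.arg(mode)
  s <- if (inherits(graph, "cell_graph")) normalized_adjacency(graph) else graph
  if (mode == "hgcn") {
    xs <- as.matrix(s %*% as.matrix(x))
    fw <- forward_hgcn(x, xs, params, config, training = FALSE)
    list(logits = fw$logits, embedding = cbind(fw$q, fw$p),
         state = phase_state(fw$q, fw$p))
  } else {
    fw <- forward_gcn(x, s, params, config, training = FALSE)
    list(logits = fw$logits, embedding = fw$top)
  }
}
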