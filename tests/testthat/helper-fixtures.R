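## Shared fixtures, built once per test run and memoised in this environment.
## All generators are seeded, so fixtures are identical across runs.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- make()
  .fixtures[[name]]
}

## Small multiome for unit tests (fast).
small_multiome <- function() {
  fixture("small_multiome", function() {
    make_multiome(synthetic_spec(n_cells = 240, rna_dim = 120, atac_dim = 140,
                                 seed = 101))
  })
}

## The default 2,000-cell study fixture, preprocessed (expensive; shared by
## the end-to-end / robustness / leakage tests).
study_multiome <- function() {
  fixture("study_multiome", function() {
    data <- make_multiome(synthetic_spec(seed = 1))
    prep <- preprocess_multiome(data$rna, data$atac)
    list(data = data, prep = prep)
  })
}

## Over-smoothing SBM fixture: 200 nodes, 4 blocks, moderate mixing so deep
## averaging homogenizes classes (the regime the diagnostic targets).
sbm_fixture <- function(seed = 1) {
  make_sbm_graph(200, 4, p_in = 0.2, p_out = 0.05, feature_dim = 8,
                 seed = seed)
}

## Desk-scale training configuration (small hidden width, short budget).
desk_config <- function(...) {
  args <- utils::modifyList(list(hidden_dim = 16, epochs = 100,
                                 patience = 50), list(...))
  do.call(model_config, args)
}

## Central finite differences of a scalar function of a matrix argument.
fd_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (ii in seq_along(x)) {
    xa <- x; xa[ii] <- xa[ii] + eps
    xb <- x; xb[ii] <- xb[ii] - eps
    g[ii] <- (f(xa) - f(xb)) / (2 * eps)
  }
  g
}

## Random mlp-variant Hamiltonian spec with biases away from relu kinks.
random_mlp_spec <- function(h, seed) {
  set.seed(seed)
  params <- list(w1 = matrix(rnorm(4 * h * 2 * h, 0, 0.4), 4 * h, 2 * h),
                 b1 = rnorm(4 * h, 0, 0.3), w2 = rnorm(4 * h, 0, 0.4),
                 b2 = rnorm(1, 0.2, 0.1))
  hamiltonian_spec("mlp", hidden_dim = h, params = params)
}
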