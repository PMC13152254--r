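test_that("gcn_layer equals the dense propagation formula", {
  ## 2 nodes, 1 edge, identity weights: every entry 0.5
  g <- cell_graph(2, rbind(c(0, 1)))
  out <- gcn_layer(diag(2), g, diag(2), activation = "none")
  expect_equal(out, matrix(0.5, 2, 2), ignore_attr = TRUE)
  ## empty edge set: self-loops only -> sigma(X W)
  g0 <- cell_graph(3, matrix(integer(), ncol = 2))
  x <- matrix(rnorm(9), 3, 3)
  expect_equal(gcn_layer(x, g0, diag(3), "none"), x, ignore_attr = TRUE)
  expect_equal(gcn_layer(x, g0, diag(3), "relu"), pmax(x, 0),
               ignore_attr = TRUE)
  ## random graphs against the dense oracle
  set.seed(10)
  for (rep in 1:10) {
    sb <- make_sbm_graph(10, 2, 0.5, 0.2, 4, seed = rep)
    w <- matrix(rnorm(4 * 3), 4, 3)
    a <- as.matrix(adjacency_matrix(sb$graph)) + diag(10)
    dm <- diag(1 / sqrt(rowSums(a)))
    dense <- pmax(dm %*% a %*% dm %*% sb$x %*% w, 0)
    expect_equal(gcn_layer(sb$x, sb$graph, w, "relu"), dense,
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("hamiltonian energies are non-negative, bounded, and scale correctly", {
  h <- 4
  spec <- random_mlp_spec(h, seed = 2)
  set.seed(3)
  q <- matrix(rnorm(6 * h), 6, h); p <- matrix(rnorm(6 * h), 6, h)
  e <- hamiltonian_energy(phase_state(q, p), spec)
  expect_gte(e, 0)
  ## duplicating all nodes scales the l2-over-nodes energy by sqrt(2)
  e2 <- hamiltonian_energy(phase_state(rbind(q, q), rbind(p, p)), spec)
  expect_equal(e2, sqrt(2) * e, tolerance = 1e-12)
  ## all-zero parameters give zero energy
  z <- hamiltonian_spec("mlp", hidden_dim = h, params = list(
    w1 = matrix(0, 4 * h, 2 * h), b1 = numeric(4 * h),
    w2 = numeric(4 * h), b2 = 0))
  expect_equal(hamiltonian_energy(phase_state(q, p), z), 0)
  ## gcn variant: tanh-bounded energy obeys the operator-norm bound
  sb <- make_sbm_graph(6, 2, 0.8, 0.3, 3, seed = 4)
  sg <- hamiltonian_spec("gcn", hidden_dim = h, graph = sb$graph, seed = 5)
  eg <- hamiltonian_energy(phase_state(q, p), sg)
  expect_gte(eg, 0)
  ## |tanh| < 1, S has unit spectral norm, so ||S T W|| <= ||T||_F ||W||_2
  bound <- sum(svd(sg$params$w_g1)$d[1]^2) * 6 * 4 * h
  expect_lte(eg, bound)
  expect_error(hamiltonian_energy(phase_state(q * NA, p), spec),
               class = "hamgcn_invalid_input")
})

test_that("hamiltonian_gradients match central finite differences (both variants)", {
  h <- 3; n <- 5
  sb <- make_sbm_graph(n, 2, 0.8, 0.3, 2, seed = 6)
  specs <- list(
    mlp = random_mlp_spec(h, seed = 7),
    gcn = hamiltonian_spec("gcn", hidden_dim = h, graph = sb$graph, seed = 8),
    quadratic = hamiltonian_spec("quadratic"),
    example = hamiltonian_spec("example", graph = sb$graph, sigma = 0.3)
  )
  set.seed(9)
  for (nm in names(specs)) {
    for (trial in 1:5) {
      q <- matrix(rnorm(n * h), n, h)
      p <- matrix(rnorm(n * h), n, h)
      g <- hamiltonian_gradients(phase_state(q, p), specs[[nm]])
      fq <- fd_grad(function(qq) {
        hamiltonian_energy(phase_state(qq, p), specs[[nm]])
      }, q)
      fp <- fd_grad(function(pp) {
        hamiltonian_energy(phase_state(q, pp), specs[[nm]])
      }, p)
      expect_equal(g$dq, fq, tolerance = 1e-4, ignore_attr = TRUE)
      expect_equal(g$dp, fp, tolerance = 1e-4, ignore_attr = TRUE)
    }
  }
  ## closed forms: quadratic gradient is (q, p); zero parameters give zero
  q <- matrix(rnorm(n * h), n, h); p <- matrix(rnorm(n * h), n, h)
  gq <- hamiltonian_gradients(phase_state(q, p), specs$quadratic)
  expect_identical(gq$dq, q)
  expect_identical(gq$dp, p)
})

test_that("example hamiltonian is positive definite in p with sin^2 wells", {
  sb <- make_sbm_graph(6, 2, 0.8, 0.3, 2, seed = 11)
  a <- as.matrix(adjacency_matrix(sb$graph))
  sigma <- 0.2
  set.seed(12)
  for (i in 1:20) {
    q <- matrix(rnorm(12), 6, 2); p <- matrix(rnorm(12), 6, 2)
    t_term <- example_hamiltonian(q, p, a, sigma) - sum(sin(q)^2)
    expect_gte(t_term, sigma * sum(p^2) - 1e-10)
  }
  ## p = 0 leaves only the potential
  q <- matrix(rnorm(12), 6, 2)
  expect_equal(example_hamiltonian(q, q * 0, a, sigma), sum(sin(q)^2))
  ## q = n*pi, p = 0 is a stationary zero-energy point
  qpi <- matrix(pi * sample(-2:2, 12, TRUE), 6, 2)
  expect_equal(example_hamiltonian(qpi, qpi * 0, a, sigma), 0,
               tolerance = 1e-12)
  spec <- hamiltonian_spec("example", graph = sb$graph, sigma = sigma)
  g <- hamiltonian_gradients(phase_state(qpi, qpi * 0), spec)
  expect_equal(max(abs(g$dq)), 0, tolerance = 1e-10)
  expect_equal(max(abs(g$dp)), 0, tolerance = 1e-10)
  expect_error(hamiltonian_spec("example", graph = sb$graph, sigma = -1),
               "positive")
  expect_error(example_hamiltonian(q, q, a, 0), "positive")
})

test_that("symplectic euler step matches the hand-computed update", {
  spec <- hamiltonian_spec("quadratic")
  st <- symplectic_euler_step(phase_state(matrix(1), matrix(0)), spec, 0.2)
  expect_equal(st$p[1, 1], -0.2, tolerance = 1e-15)
  expect_equal(st$q[1, 1], 0.96, tolerance = 1e-15)
  ## zero-gradient hamiltonian leaves the state unchanged
  h <- 2
  z <- hamiltonian_spec("mlp", hidden_dim = h, params = list(
    w1 = matrix(0, 4 * h, 2 * h), b1 = numeric(4 * h),
    w2 = numeric(4 * h), b2 = 0))
  q <- matrix(rnorm(6), 3, 2); p <- matrix(rnorm(6), 3, 2)
  st2 <- symplectic_euler_step(phase_state(q, p), z, 0.2)
  expect_identical(st2$q, q)
  expect_identical(st2$p, p)
  expect_error(symplectic_euler_step(phase_state(q, p), z, 0), "positive")
})

test_that("one-step map is symplectic: unit jacobian determinant", {
  spec <- hamiltonian_spec("quadratic")
  dt <- 0.2
  stepmap <- function(z) {
    st <- symplectic_euler_step(phase_state(matrix(z[1]), matrix(z[2])),
                                spec, dt)
    c(st$q[1, 1], st$p[1, 1])
  }
  z0 <- c(0.7, -0.3)
  eps <- 1e-6
  jac <- matrix(0, 2, 2)
  for (j in 1:2) {
    za <- z0; za[j] <- za[j] + eps
    zb <- z0; zb[j] <- zb[j] - eps
    jac[, j] <- (stepmap(za) - stepmap(zb)) / (2 * eps)
  }
  expect_equal(det(jac), 1, tolerance = 1e-9)
})

test_that("integrate_phase does the right number of steps and bounds energy", {
  spec <- hamiltonian_spec("quadratic")
  st <- phase_state(matrix(1), matrix(0))
  res <- integrate_phase(st, spec, dt = 0.2, horizon = c(0, 1))
  expect_equal(res$n_steps, 5L)
  ## zero-length horizon is the identity
  res0 <- integrate_phase(st, spec, dt = 0.2, horizon = c(0, 0))
  expect_identical(res0$state$q, st$q)
  ## harmonic oscillator, 10,000 steps at dt = 0.01: energy within 1%
  long <- integrate_phase(st, spec, dt = 0.01, horizon = c(0, 100),
                          record = TRUE)
  expect_equal(long$n_steps, 10000L)
  rel <- abs(long$energies - long$energies[1]) / long$energies[1]
  expect_lt(max(rel), 0.01)
})

test_that("phase_init splits the projection into q and p deterministically", {
  set.seed(20)
  sb <- make_sbm_graph(12, 2, 0.6, 0.2, 5, seed = 3)
  h <- 4
  params <- list(w_enc = matrix(rnorm(5 * h), 5, h),
                 w_proj = matrix(rnorm(h * 2 * h), h, 2 * h),
                 b_proj = rnorm(2 * h))
  st <- phase_init(sb$x, sb$graph, params)
  expect_equal(dim(st$q), c(12, h))
  expect_equal(dim(st$p), c(12, h))
  ## eval mode is bit-deterministic
  expect_identical(phase_init(sb$x, sb$graph, params), st)
  ## zero projection: q0 = p0 = 0
  params0 <- params
  params0$w_proj[] <- 0; params0$b_proj[] <- 0
  st0 <- phase_init(sb$x, sb$graph, params0)
  expect_true(all(st0$q == 0) && all(st0$p == 0))
  ## manual composition equals the op
  z <- gcn_layer(sb$x, sb$graph, params$w_enc, "relu")
  y0 <- sweep(z %*% params$w_proj, 2, params$b_proj, "+")
  expect_equal(st$q, y0[, 1:h], ignore_attr = TRUE)
  expect_equal(st$p, y0[, h + 1:h], ignore_attr = TRUE)
})

test_that("readout gives uniform probabilities for zero heads", {
  st <- phase_state(matrix(rnorm(10), 5, 2), matrix(rnorm(10), 5, 2))
  head <- list(w = matrix(0, 4, 16), b = numeric(16))
  logits <- readout_classify(st, head)
  pr <- exp(logits) / rowSums(exp(logits))
  expect_equal(pr, matrix(1 / 16, 5, 16), ignore_attr = TRUE)
  ## q-only readout uses half the phase state
  headq <- list(w = matrix(rnorm(2 * 3), 2, 3), b = numeric(3))
  lq <- readout_classify(st, headq, head_input = "q")
  expect_equal(lq, st$q %*% headq$w, ignore_attr = TRUE)
})

test_that("training-mode backprop matches finite differences end to end", {
  set.seed(7)
  n <- 6; f <- 4; h <- 3
  sb <- make_sbm_graph(n, 2, 0.9, 0.3, f, seed = 2)
  s <- normalized_adjacency(sb$graph)
  xs <- as.matrix(s %*% sb$x)
  y <- as.integer(sb$labels)
  cfg <- model_config(hidden_dim = h, dropout = 0, epochs = 1, seed = 11)
  params <- hamgcn:::init_params("hgcn", f, cfg, 2L)
  params$b_proj <- rnorm(2 * h, 0, 0.1)   # move off relu kinks
  loss_fn <- function(pp) {
    fw <- hamgcn:::forward_hgcn(sb$x, xs, pp, cfg, FALSE)
    cross_entropy(fw$logits[[1]], y, 1:n)
  }
  fw <- hamgcn:::forward_hgcn(sb$x, xs, params, cfg, FALSE)
  dl <- list(hamgcn:::ce_grad(fw$logits[[1]], y, 1:n, 1))
  gr <- hamgcn:::backward_hgcn(fw, xs, params, cfg, dl)
  for (nm in names(params)) {
    fd <- fd_grad(function(v) {
      pp <- params; pp[[nm]] <- v; loss_fn(pp)
    }, params[[nm]], eps = 1e-6)
    expect_equal(as.numeric(gr[[nm]]), as.numeric(fd), tolerance = 1e-5,
                 ignore_attr = TRUE, label = paste("grad", nm))
  }
})

test_that("hgcn with zero-length horizon reduces to encoder + head", {
  set.seed(31)
  sb <- make_sbm_graph(10, 2, 0.6, 0.2, 4, seed = 5)
  cfg <- model_config(hidden_dim = 3, dropout = 0, horizon = c(0, 0),
                      seed = 2)
  params <- hamgcn:::init_params("hgcn", 4, cfg, 2L)
  out <- hamgcn_forward(sb$x, sb$graph, params, cfg, "hgcn")
  z <- gcn_layer(sb$x, sb$graph, params$w_enc, "relu")
  y0 <- sweep(z %*% params$w_proj, 2, params$b_proj, "+")
  manual <- sweep(y0 %*% params$head_w_1, 2, params$head_b_1, "+")
  expect_equal(out$logits[[1]], manual, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("gcn baseline depth 1 equals the dense one-layer formula + head", {
  set.seed(33)
  sb <- make_sbm_graph(10, 2, 0.6, 0.2, 4, seed = 6)
  cfg <- model_config(hidden_dim = 3, dropout = 0, depth = 1, seed = 2)
  params <- hamgcn:::init_params("gcn_baseline", 4, cfg, 2L)
  out <- hamgcn_forward(sb$x, sb$graph, params, cfg, "gcn_baseline")
  a <- as.matrix(adjacency_matrix(sb$graph)) + diag(10)
  dm <- diag(1 / sqrt(rowSums(a)))
  hidden <- pmax(dm %*% a %*% dm %*% sb$x %*% params$w_1, 0)
  manual <- sweep(hidden %*% params$head_w_1, 2, params$head_b_1, "+")
  expect_equal(out$logits[[1]], manual, tolerance = 1e-10,
               ignore_attr = TRUE)
})
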