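#' Phase-space state of node embeddings
#'
#' Paired position (`q`) and momentum (`p`) matrices, one row per cell, H
#' columns each. This is the object the symplectic integrator evolves.
#'
#' @param q,p numeric matrices of identical shape (N x H), all finite.
#' @return a `phase_state` object.
#' @export
phase_state <- function(q, p) {
  q <- as.matrix(q); p <- as.matrix(p)
  if (!identical(dim(q), dim(p))) stop_hamgcn("q and p must have the same shape")
  assert_finite(q, "q"); assert_finite(p, "p")
  structure(list(q = q, p = p), class = "phase_state")
}

#' @export
print.phase_state <- function(x, ...) {
  cat(sprintf("<phase_state> %d nodes x %d dims (phase dim %d)\n",
              nrow(x$q), ncol(x$q), 2L * ncol(x$q)))
  invisible(x)
}

#' Single graph-convolution layer
#'
#' Computes \eqn{\sigma(\tilde{D}^{-1/2}(A+I)\tilde{D}^{-1/2} X W)} — the
#' symmetric-normalized neighborhood average with self-loops, followed by a
#' learnable linear map and optional ReLU. Evaluated sparsely but numerically
#' equal to the dense formula; isolated nodes are fine (the self-loop gives
#' them degree 1).
#'
#' @param x N x F numeric matrix of node features.
#' @param graph a [cell_graph()] with N nodes, or a precomputed normalized
#'   adjacency from [normalized_adjacency()].
#' @param w F x F' weight matrix.
#' @param activation `"relu"` or `"none"`.
#' @return N x F' matrix.
#' @export
gcn_layer <- function(x, graph, w, activation = c("relu", "none")) {
  activation <- match.arg(activation)
  s <- if (inherits(graph, "cell_graph")) normalized_adjacency(graph) else graph
  x <- as.matrix(x)
  if (nrow(x) != nrow(s)) stop_hamgcn("feature row count must match graph size")
  if (ncol(x) != nrow(as.matrix(w))) stop_hamgcn("weight shape mismatch")
  out <- as.matrix(s %*% x %*% w)
  if (activation == "relu") out <- relu(out)
  out
}

## ---- Hamiltonian specifications --------------------------------------------

#' Specification of the scalar energy function H(q, p)
#'
#' Four variants:
#' \describe{
#'   \item{`mlp`}{default; per node, `(q_i || p_i)` passes through
#'     Linear(2H -> 4H) -> ReLU -> Linear(4H -> 1), and the energy is the
#'     l2 norm of the per-node scalars over nodes. This is the energy used in
#'     all learned forward passes.}
#'   \item{`gcn`}{`||g1(tanh(g2(q || p)))||^2` with `g1`, `g2` graph
#'     convolutions over `graph`; the tanh keeps the energy
#'     bounded-input-bounded-output.}
#'   \item{`quadratic`}{the separable test Hamiltonian
#'     `1/2 (||q||^2 + ||p||^2)`; closed-form gradients, used to validate the
#'     integrator.}
#'   \item{`example`}{the constructive kinetic + potential test energy; see
#'     [example_hamiltonian()].}
#' }
#'
#' @param variant one of `"mlp"`, `"gcn"`, `"quadratic"`, `"example"`.
#' @param hidden_dim H, the per-coordinate embedding width (needed to size
#'   parameters for `mlp`/`gcn`).
#' @param graph a [cell_graph()]; required for `gcn` and `example`.
#' @param params optional named list of parameter matrices; initialized
#'   (Glorot-uniform, seeded) when missing.
#' @param seed seed for parameter initialization.
#' @param sigma positive constant of the `example` kinetic term.
#' @return a `hamiltonian_spec` object.
#' @export
hamiltonian_spec <- function(variant = c("mlp", "gcn", "quadratic", "example"),
                             hidden_dim = NULL, graph = NULL, params = NULL,
                             seed = 1, sigma = 0.1) {
  variant <- match.arg(variant)
  spec <- list(variant = variant, hidden_dim = hidden_dim, sigma = sigma)
  if (variant %in% c("gcn", "example")) {
    if (is.null(graph)) stop_hamgcn("variant '", variant, "' requires a graph")
  }
  if (variant == "gcn") {
    spec$s <- if (inherits(graph, "cell_graph")) normalized_adjacency(graph) else graph
  }
  if (variant == "example") {
    spec$a_g <- if (inherits(graph, "cell_graph")) {
      as.matrix(adjacency_matrix(graph))
    } else {
      as.matrix(graph)
    }
    if (sigma <= 0) stop_hamgcn("sigma must be positive")
  }
  if (variant == "mlp") {
    h <- hidden_dim
    if (is.null(h)) stop_hamgcn("mlp variant requires hidden_dim")
    if (is.null(params)) {
      params <- with_seed(seed, list(
        w1 = glorot(4L * h, 2L * h), b1 = numeric(4L * h),
        w2 = as.numeric(glorot(4L * h, 1L)), b2 = 0
      ))
    }
    spec$params <- params
  }
  if (variant == "gcn") {
    h <- hidden_dim
    if (is.null(h)) stop_hamgcn("gcn variant requires hidden_dim")
    if (is.null(params)) {
      params <- with_seed(seed, list(
        w_g2 = glorot(2L * h, 4L * h),   # first conv: 2H -> 4H
        w_g1 = glorot(4L * h, 1L)        # second conv: 4H -> 1
      ))
    }
    spec$params <- params
  }
  structure(spec, class = "hamiltonian_spec")
}

#' Raw adjacency (with no self-loops) as a sparse matrix
#' @param g a [cell_graph()].
#' @return sparse symmetric 0/1 Matrix.
#' @export
adjacency_matrix <- function(g) {
  e <- g$edges
  if (nrow(e) == 0) {
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(g$n_nodes, g$n_nodes)))
  }
  Matrix::sparseMatrix(i = c(e[, 1], e[, 2]) + 1L, j = c(e[, 2], e[, 1]) + 1L,
                       x = 1, dims = c(g$n_nodes, g$n_nodes))
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

## Forward cache for the mlp energy at a given (q, p): everything the
## gradient, Hessian-vector product and parameter VJP reuse.
mlp_energy_cache <- function(q, p, params) {
  z <- cbind(q, p)                       # N x 2H
  a <- sweep(z %*% t(params$w1), 2L, params$b1, "+")  # N x 4H
  d <- (a > 0) * 1                        # relu'
  hh <- a * d                             # relu(a)
  e <- as.numeric(hh %*% params$w2) + params$b2       # per-node scalar
  r <- sqrt(sum(e * e))                   # energy = l2 over nodes
  dw <- sweep(d, 2L, params$w2, "*")      # rows: d_j (.) w2
  list(z = z, a = a, d = d, hh = hh, e = e, r = r, dw = dw)
}

mlp_energy_grad <- function(cache, params) {
  n <- nrow(cache$z)
  if (cache$r == 0) {
    return(matrix(0, n, ncol(cache$z)))
  }
  (cache$dw * (cache$e / cache$r)) %*% params$w1    # N x 2H
}

## Hessian-vector product of the mlp energy at the cached point applied to a
## phase-space direction v (N x 2H). ReLU second derivatives vanish a.e., so
## the Hessian is rank-structured: (Hv)_j = g_j [s_j / r - e_j <e, s> / r^3]
## with g_j = W1' (d_j . w2) and s_j = g_j' v_j.
mlp_energy_hvp <- function(cache, params, v) {
  n <- nrow(cache$z)
  if (cache$r == 0) return(matrix(0, n, ncol(cache$z)))
  gmat <- cache$dw %*% params$w1          # N x 2H, rows g_j
  s <- rowSums(gmat * v)
  coef <- s / cache$r - cache$e * sum(cache$e * s) / cache$r^3
  gmat * coef
}

## Gradient w.r.t. the energy parameters of sum_j u_j' grad_z_j H, the
## quantity backprop needs when an integrator step used grad H with upstream
## sensitivity u (N x 2H). Derived analytically; relu'' = 0 a.e.
mlp_energy_param_vjp <- function(cache, params, u) {
  r <- cache$r
  zero <- list(w1 = matrix(0, nrow(params$w1), ncol(params$w1)),
               b1 = numeric(length(params$b1)),
               w2 = numeric(length(params$w2)), b2 = 0)
  if (r == 0) return(zero)
  cc <- u %*% t(params$w1)               # N x 4H, rows W1 u_j
  m <- cache$d * cc
  s <- as.numeric(m %*% params$w2)       # s_j = g_j' u_j
  sum_es <- sum(cache$e * s)
  alpha <- s / r - cache$e * sum_es / r^3
  er <- cache$e / r
  list(
    w1 = t(cache$dw * er) %*% u + t(cache$dw * alpha) %*% cache$z,
    b1 = colSums(cache$dw * alpha),
    w2 = colSums(m * er) + colSums(cache$hh * alpha),
    b2 = sum(alpha)
  )
}

#' Scalar energy of a phase state
#'
#' Evaluates the Hamiltonian defined by `spec` at `state`. Always a single
#' finite non-negative number for finite input.
#'
#' @param state a [phase_state()].
#' @param spec a [hamiltonian_spec()].
#' @return non-negative scalar.
#' @export
hamiltonian_energy <- function(state, spec) {
  assert_finite(state$q, "q"); assert_finite(state$p, "p")
  switch(spec$variant,
    mlp = mlp_energy_cache(state$q, state$p, spec$params)$r,
    gcn = {
      z <- cbind(state$q, state$p)
      t1 <- tanh(as.matrix(spec$s %*% z %*% spec$params$w_g2))
      b <- as.matrix(spec$s %*% t1 %*% spec$params$w_g1)
      sum(b * b)
    },
    quadratic = 0.5 * (sum(state$q^2) + sum(state$p^2)),
    example = example_hamiltonian(state$q, state$p, spec$a_g, spec$sigma)
  )
}

#' Exact gradients of the energy with respect to q and p
#'
#' Hand-derived partial derivatives for every variant; validated against
#' central finite differences in the test suite. These are the quantities
#' the symplectic integrator consumes.
#'
#' @param state a [phase_state()].
#' @param spec a [hamiltonian_spec()].
#' @return list with matrices `dq` and `dp` (each N x H).
#' @export
hamiltonian_gradients <- function(state, spec) {
  h <- ncol(state$q)
  switch(spec$variant,
    mlp = {
      cache <- mlp_energy_cache(state$q, state$p, spec$params)
      g <- mlp_energy_grad(cache, spec$params)
      list(dq = g[, seq_len(h), drop = FALSE],
           dp = g[, h + seq_len(h), drop = FALSE])
    },
    gcn = {
      z <- cbind(state$q, state$p)
      a1 <- as.matrix(spec$s %*% z %*% spec$params$w_g2)
      t1 <- tanh(a1)
      b <- as.matrix(spec$s %*% t1 %*% spec$params$w_g1)
      dt1 <- as.matrix(spec$s %*% (2 * b) %*% t(spec$params$w_g1))
      da1 <- dt1 * (1 - t1^2)
      dz <- as.matrix(spec$s %*% da1 %*% t(spec$params$w_g2))
      list(dq = dz[, seq_len(h), drop = FALSE],
           dp = dz[, h + seq_len(h), drop = FALSE])
    },
    quadratic = list(dq = state$q, dp = state$p),
    example = {
      a <- spec$a_g
      aq <- a %*% state$q                       # N x H, columns A q_k
      c_k <- colSums(state$p * aq)              # p_k' A q_k per column
      dq <- t(a) %*% sweep(state$p, 2L, 2 * c_k, "*")
      dp <- sweep(aq, 2L, 2 * c_k, "*") + 2 * spec$sigma * state$p +
        ## potential term contributes only to dq
        0
      dq <- as.matrix(dq) + sin(2 * state$q)    # d/dq ||sin q||^2
      list(dq = dq, dp = as.matrix(dp))
    }
  )
}

#' Constructive kinetic + potential test Hamiltonian
#'
#' `T(q, p) = sum_k [ (p_k' A q_k)^2 + sigma ||p_k||^2 ]` over embedding
#' columns `k`, plus `V(q) = ||sin q||^2`. The kinetic quadratic form is
#' positive definite in `p` (`T >= sigma ||p||^2`), and the sine-squared
#' potential has strict local minima at `q = n * pi`, giving multiple stable
#' equilibria. Used only as a fixed integrator-validation energy, never
#' trained.
#'
#' @param q,p N x H matrices.
#' @param a_g N x N (adjacency-like) matrix.
#' @param sigma positive scalar.
#' @return non-negative scalar energy.
#' @export
example_hamiltonian <- function(q, p, a_g, sigma) {
  if (sigma <= 0) stop_hamgcn("sigma must be positive")
  aq <- as.matrix(a_g %*% q)
  c_k <- colSums(p * aq)
  sum(c_k^2) + sigma * sum(p^2) + sum(sin(q)^2)
}

## ---- Symplectic integration -------------------------------------------------

#' One symplectic Euler step
#'
#' Staggered explicit update: the momentum moves first using the energy
#' gradient at the current state, then the position moves using the gradient
#' evaluated at the *updated* momentum:
#' `p' = p - dt * dH/dq(q, p)`, `q' = q + dt * dH/dp(q, p')`.
#' For separable Hamiltonians this map is exactly symplectic (unit Jacobian
#' determinant); for the learned non-separable energies it is the standard
#' explicit approximation of semi-implicit symplectic Euler.
#'
#' @param state a [phase_state()].
#' @param spec a [hamiltonian_spec()].
#' @param dt positive step size.
#' @return the advanced [phase_state()].
#' @export
#' @examples
#' s <- phase_state(matrix(1), matrix(0))
#' spec <- hamiltonian_spec("quadratic")
#' symplectic_euler_step(s, spec, dt = 0.2)  # q = 0.96, p = -0.2
symplectic_euler_step <- function(state, spec, dt) {
  if (dt <= 0) stop_hamgcn("dt must be positive")
  g1 <- hamiltonian_gradients(state, spec)
  p1 <- state$p - dt * g1$dq
  g2 <- hamiltonian_gradients(phase_state(state$q, p1), spec)
  q1 <- state$q + dt * g2$dp
  phase_state(q1, p1)
}

#' Integrate the phase state over a time horizon
#'
#' Applies `round((end - start) / dt)` symplectic Euler steps (5 with the
#' default `dt = 0.2` on `[0, 1]`). With `record = TRUE` the energy is
#' evaluated at the initial state and after every step and returned as an
#' `energies` attribute-free vector alongside the state.
#'
#' @param state a [phase_state()].
#' @param spec a [hamiltonian_spec()].
#' @param dt step size, default 0.2.
#' @param horizon length-2 numeric `c(start, end)`.
#' @param record logical; record per-step energies.
#' @return list with `state` (final [phase_state()]), `n_steps`, and
#'   `energies` (length `n_steps + 1`, `NULL` unless `record`).
#' @export
integrate_phase <- function(state, spec, dt = 0.2, horizon = c(0, 1),
                            record = FALSE) {
  if (horizon[2] < horizon[1]) stop_hamgcn("horizon end must be >= start")
  n_steps <- as.integer(round((horizon[2] - horizon[1]) / dt))
  energies <- if (record) numeric(n_steps + 1L) else NULL
  if (record) energies[1L] <- hamiltonian_energy(state, spec)
  for (t in seq_len(n_steps)) {
    state <- symplectic_euler_step(state, spec, dt)
    if (record) energies[t + 1L] <- hamiltonian_energy(state, spec)
  }
  list(state = state, n_steps = n_steps, energies = energies)
}
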