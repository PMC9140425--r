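# Independent oracles used across the suite.

# all 2^N spin states, one per column
all_states <- function(N) {
  M <- matrix(-1, N, 2^N)
  for (i in seq_len(N))
    M[i, ] <- rep(rep(c(-1, 1), each = 2^(i - 1)), length.out = 2^N)
  M
}

# exact successor distribution of a kinetic Ising net from state s (brute
# force over all 2^N successors via the per-spin product formula)
exact_successor_probs <- function(net, x, s) {
  S <- all_states(net$N)
  H <- compute_field(net, x, s)
  p_up <- stats::plogis(2 * net$beta * H)
  apply(S, 2, function(sn) prod(ifelse(sn > 0, p_up, 1 - p_up)))
}

# exact stationary distribution of the zero-input chain by power iteration
# on the 2^N-state kernel
exact_stationary <- function(net, iters = 2000, tol = 1e-14) {
  S <- all_states(net$N)
  K <- 2^net$N
  P <- matrix(0, K, K)
  for (j in seq_len(K))
    P[j, ] <- exact_successor_probs(net, NULL, S[, j])
  pi0 <- rep(1 / K, K)
  for (k in seq_len(iters)) {
    pi1 <- drop(pi0 %*% P)
    if (max(abs(pi1 - pi0)) < tol) break
    pi0 <- pi1
  }
  list(pi = pi0, P = P, S = S)
}

# exact one-step-delayed correlation B_ij = <s_i(t+1) s_j(t)> at stationarity
exact_delayed_correlation <- function(net) {
  st <- exact_stationary(net)
  S <- st$S; P <- st$P; pi <- st$pi
  N <- net$N
  B <- matrix(0, N, N)
  for (j in seq_len(2^N)) {
    Es_next <- drop(S %*% P[j, ])          # E[s(t+1) | s(t) = S[,j]]
    B <- B + pi[j] * tcrossprod(Es_next, S[, j])
  }
  B
}

# stationary covariance of dx/dt = M x + xi, xi ~ N(0, Sigma): solves the
# continuous Lyapunov equation M P + P M' + Sigma = 0 via vectorization
lyapunov_cov <- function(M, Sigma) {
  d <- nrow(M)
  A <- kronecker(diag(d), M) + kronecker(M, diag(d))
  matrix(solve(A, -as.vector(Sigma)), d, d)
}

# small random kinetic Ising net for fixtures
random_net <- function(N, beta = 0.5, scale = 0.3, seed = 1, Phi = NULL) {
  set.seed(seed)
  kinetic_ising_net(matrix(rnorm(N * N, sd = scale), N, N), beta = beta,
                    Phi = Phi)
}
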