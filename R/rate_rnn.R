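#' Construct a continuous rate recurrent network
#'
#' Standard leaky tanh-rate dynamics,
#' \deqn{\tau \dot u = -u + J r + w_{in} f(t), \qquad r = \tanh(u),}
#' with a linear readout \eqn{z = w^T r}. The recurrent weights and readout
#' are trained online by recursive least squares (see [rls_update()] and
#' [train_rate_rnn()]). The rate dynamics themselves are conventional
#' reservoir plumbing; the learning steps are the exact rank-one updates.
#'
#' @param N network size.
#' @param d input/target dimension.
#' @param tau unit time constant (time).
#' @param g initial recurrent weight scale (entries
#'   \eqn{N(0, g^2/N)}).
#' @param rho RLS regularizer: \code{P} is initialized to
#'   \code{(1/rho) * I}.
#' @param Delta steps between learning updates.
#' @param dt integration step.
#' @param seed integer seed or \code{NULL}.
#' @return An object of class \code{"rate_rnn"}.
#' @export
rate_rnn <- function(N = 100, d = 1, tau = 1, g = 1.2, rho = 1,
                     Delta = 2L, dt = 0.1, seed = NULL) {
  stopifnot(N >= d, tau > 0, g >= 0, rho > 0, Delta >= 1)
  if (!is.null(seed)) set.seed(seed)
  structure(list(
    J = matrix(stats::rnorm(N * N, sd = g / sqrt(N)), N, N),
    readout = matrix(0, d, N),
    w_in = matrix(stats::rnorm(N * d), N, d),
    P = diag(1 / rho, N, N),
    N = N, d = d, tau = tau, g = g, rho = rho, Delta = as.integer(Delta),
    dt = dt, u = stats::rnorm(N, sd = 0.1), trained = FALSE),
    class = "rate_rnn")
}

#' @export
print.rate_rnn <- function(x, ...) {
  cat("Rate RNN: N =", x$N, ", d =", x$d, ", tau =", x$tau,
      ", g =", x$g, if (x$trained) "(trained)" else "(untrained)", "\n")
  cat("  dominant timescale:", signif(dominant_timescale(x$J), 3), "\n")
  invisible(x)
}

#' @export
coef.rate_rnn <- function(object, ...) object$J

#' One recursive-least-squares update
#'
#' Rank-one Sherman-Morrison update of the running inverse correlation
#' matrix followed by the error-gated weight step:
#' \deqn{P \leftarrow P - \frac{P r r^T P}{1 + r^T P r}, \qquad
#'       W \leftarrow W - e (P r)^T.}
#' With \eqn{P} initialized to \eqn{(1/\rho) I} and the error computed from
#' the pre-update weights, the streamed solution coincides exactly with
#' batch ridge regression with penalty \eqn{\rho}.
#'
#' @param W weight matrix being trained (\code{m x N}).
#' @param P running inverse correlation matrix (\code{N x N}, symmetric
#'   positive definite).
#' @param e error vector (length \code{m}), computed with the current
#'   \code{W}.
#' @param r rate/regressor vector (length \code{N}).
#' @return List with updated \code{W} and \code{P}.
#' @export
rls_update <- function(W, P, e, r) {
  if (!all(is.finite(e)))
    stop("non-finite error in RLS update; training diverged")
  Pr <- P %*% r
  k <- drop(1 + crossprod(r, Pr))
  P <- P - tcrossprod(Pr) / k
  W <- W - outer(drop(e), drop(P %*% r))
  list(W = W, P = P)
}

#' Train a rate RNN to encode a dynamic target
#'
#' Input and target are the same signal: the network is driven by the
#' stimulus and trained so that its linear readout reproduces it. Each
#' learning step (every \code{Delta} integration steps) uses the readout
#' error \eqn{e_z = z - f}; the readout is updated directly and the
#' recurrent weights receive the error fed back along the input pathway
#' (\eqn{e = w_{in} e_z}), so the learned recurrent component internalizes
#' the target dynamics. Performance is the correlation between readout and
#' target on a held-out run through the same trajectory.
#'
#' @param traj target trajectory (\code{"stim_traj"} or \code{d x T}
#'   matrix).
#' @param net a [rate_rnn()]; or \code{NULL} to construct one.
#' @param N,tau,g passed to [rate_rnn()] when \code{net} is \code{NULL}.
#' @param trials number of training passes through the trajectory
#'   (\code{0} leaves the network untrained).
#' @param seed integer seed or \code{NULL}.
#' @return The trained \code{"rate_rnn"} with extra fields
#'   \code{performance} (evaluation correlation per target dimension, and
#'   its mean \code{D}), \code{z} (evaluation readout), \code{trials}.
#' @export
train_rate_rnn <- function(traj, net = NULL, N = 100, tau = 1, g = 1.2,
                           trials = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- if (inherits(traj, "stim_traj")) traj$x else as.matrix(traj)
  d <- nrow(f); T <- ncol(f)
  if (is.null(net)) net <- rate_rnn(N = N, d = d, tau = tau, g = g)
  stopifnot(inherits(net, "rate_rnn"), net$d == d)
  # keep drive and target on a unit scale so the tanh units stay sensitive
  sc <- max(abs(f)); if (sc == 0) sc <- 1
  f <- f / sc
  for (tr in seq_len(trials)) {
    run <- rnn_run(net, f, learn = TRUE)
    net <- run$net
  }
  net$trained <- net$trained || trials > 0
  eval_run <- rnn_run(net, f, learn = FALSE)
  z <- eval_run$z * sc
  per_dim <- vapply(seq_len(d), function(i) {
    if (stats::sd(z[i, ]) == 0) return(0)
    if (stats::sd(f[i, ]) == 0) return(NA_real_)  # constant target
    stats::cor(z[i, ], f[i, ] * sc)
  }, numeric(1))

  net$performance <- list(D = mean(per_dim), per_dim = per_dim)
  net$z <- z
  net$trials <- trials
  net
}

# one pass of the leaky tanh dynamics; RLS learning every Delta steps
rnn_run <- function(net, f, learn = FALSE) {
  N <- net$N; d <- net$d; T <- ncol(f)
  a <- net$dt / net$tau
  u <- net$u
  J <- net$J; W <- net$readout; P <- net$P; win <- net$w_in
  z <- matrix(0, d, T)
  for (t in seq_len(T)) {
    r <- tanh(u)
    zt <- W %*% r
    z[, t] <- zt
    if (learn && t %% net$Delta == 0) {
      ez <- drop(zt - f[, t])
      Pr <- P %*% r
      k <- drop(1 + crossprod(r, Pr))
      P <- P - tcrossprod(Pr) / k
      gain <- drop(P %*% r)
      W <- W - outer(ez, gain)
      J <- J - outer(drop(win %*% ez), gain)
    }
    u <- (1 - a) * u + a * (J %*% r + win %*% f[, t])
    if (!all(is.finite(u)))
      stop("rate dynamics diverged (g = ", net$g, ")")
    u <- drop(u)
  }
  net$J <- J; net$readout <- W; net$P <- P; net$u <- u
  list(net = net, z = z)
}

#' Dominant timescale of a connectivity matrix
#'
#' \eqn{1/|\lambda_{max}|} with \eqn{\lambda_{max}} the largest-modulus
#' eigenvalue of \code{J}; the slowest (dominating) mode of the linearized
#' dynamics. A nilpotent matrix (zero spectrum) returns \code{Inf}.
#'
#' @param J square matrix.
#' @return Time units (inverse modulus of the leading eigenvalue).
#' @export
dominant_timescale <- function(J) {
  J <- as.matrix(J)
  stopifnot(nrow(J) == ncol(J))
  lam <- eigen(J, only.values = TRUE)$values
  mx <- max(Mod(lam))
  if (mx == 0) Inf else 1 / mx
}
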