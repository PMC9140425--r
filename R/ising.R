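#' Construct a kinetic Ising network
#'
#' Discrete-time Markov dynamics over \eqn{\pm1} spins with (possibly
#' asymmetric) couplings. All spins update in parallel; given the previous
#' state the one-step transition factorizes over sites,
#' \deqn{P(s(t+1)|s(t)) = \prod_i \frac{\exp(\beta s_i(t+1) H_i(t))}
#'                                     {2\cosh(\beta H_i(t))}}
#' with local field \eqn{H_i(t) = \sum_k \Phi_{ik} x_k(t) +
#' \sum_j J_{ij} s_j(t) + b_i}.
#'
#' @param J coupling matrix (\code{N x N}), no symmetry constraint. The
#'   diagonal (self-coupling) is permitted unless \code{no_self = TRUE}.
#' @param beta inverse temperature (reliability), \code{>= 0}.
#' @param Phi optional input projection (\code{N x d}).
#' @param bias optional static field (length \code{N}); default zero.
#' @param no_self zero the diagonal of \code{J}.
#' @return An object of class \code{"kising_net"}.
#' @export
kinetic_ising_net <- function(J, beta = 0.5, Phi = NULL, bias = NULL,
                              no_self = FALSE) {
  J <- as.matrix(J)
  N <- nrow(J)
  stopifnot(ncol(J) == N, beta >= 0)
  if (!all(is.finite(J)) || !is.finite(beta))
    stop("couplings and beta must be finite")
  if (no_self) diag(J) <- 0
  if (!is.null(Phi)) {
    Phi <- as.matrix(Phi)
    if (nrow(Phi) != N)
      stop("Phi has ", nrow(Phi), " rows; expected N = ", N)
    if (!all(is.finite(Phi))) stop("Phi must be finite")
  }
  if (is.null(bias)) bias <- numeric(N)
  stopifnot(length(bias) == N, all(is.finite(bias)))
  structure(list(J = J, beta = beta, Phi = Phi, bias = bias, N = N),
            class = "kising_net")
}

#' @export
print.kising_net <- function(x, ...) {
  cat("Kinetic Ising network: N =", x$N, ", beta =", x$beta, "\n")
  cat("  asymmetry eta =", signif(asymmetry(x$J), 3), "\n")
  if (!is.null(x$Phi))
    cat("  input projection: d =", ncol(x$Phi), "\n")
  invisible(x)
}

#' Local field of a kinetic Ising network
#'
#' \eqn{H_i = \sum_k \Phi_{ik} x_k + \sum_j J_{ij} s_j + b_i}. Works on
#' single states (vectors) or whole trajectories (matrices with time in
#' columns).
#'
#' @param net a [kinetic_ising_net()].
#' @param x_t stimulus vector (length \code{d}) or \code{d x T} matrix;
#'   \code{NULL} for no input.
#' @param s_t spin vector (entries \eqn{\pm1}) or \code{N x T} matrix.
#' @return Field vector (length \code{N}) or \code{N x T} matrix.
#' @export
compute_field <- function(net, x_t, s_t) {
  stopifnot(inherits(net, "kising_net"))
  sm <- if (is.matrix(s_t)) s_t else matrix(s_t, ncol = 1)
  if (nrow(sm) != net$N)
    stop("spin state has ", nrow(sm), " rows; network has N = ", net$N)
  if (!all(sm == 1 | sm == -1)) stop("spins must be +1/-1")
  H <- net$J %*% sm + net$bias
  if (!is.null(x_t)) {
    if (is.null(net$Phi))
      stop("network has no input projection Phi but a stimulus was supplied")
    xm <- if (is.matrix(x_t)) x_t else matrix(x_t, ncol = 1)
    if (nrow(xm) != ncol(net$Phi))
      stop("stimulus has ", nrow(xm), " rows; Phi expects d = ",
           ncol(net$Phi))
    if (ncol(xm) != ncol(sm))
      stop("stimulus and spin trajectories differ in length")
    H <- H + net$Phi %*% xm
  }
  if (is.matrix(s_t)) H else drop(H)
}

#' One parallel Glauber update
#'
#' All spins update simultaneously; each is set to \eqn{+1} independently
#' with probability \eqn{e^{\beta H_i} / (2\cosh\beta H_i) =
#' \mathrm{logistic}(2\beta H_i)}.
#'
#' @inheritParams compute_field
#' @param seed integer seed or \code{NULL} (use the current RNG stream).
#' @return Next spin vector.
#' @export
ising_step <- function(net, x_t, s_t, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  H <- compute_field(net, x_t, s_t)
  p <- stats::plogis(2 * net$beta * H)
  ifelse(stats::runif(length(p)) < p, 1, -1)
}

#' Simulate a kinetic Ising network
#'
#' Iterates the parallel Glauber update, consuming one stimulus sample per
#' network step: column \code{t} of the stimulus enters the field that
#' generates spins at \code{t + 1}. The returned raster has the initial
#' state in its first column and is aligned with the stimulus.
#'
#' @param object a [kinetic_ising_net()].
#' @param nsim number of steps \code{T} (ignored when \code{stimulus} is
#'   given, which fixes \code{T}).
#' @param seed integer seed or \code{NULL}.
#' @param stimulus optional \code{"stim_traj"} or \code{d x T} matrix.
#' @param s0 initial spin vector; default an i.i.d. fair-coin draw.
#' @param mode \code{"parallel"} (default; all spins update each step) or
#'   \code{"asynchronous"} (one uniformly chosen site updates per substep,
#'   \code{N} substeps recorded per step).
#' @param ... unused.
#' @return Spin raster (\code{N x T} matrix of \eqn{\pm1}).
#' @export
simulate.kising_net <- function(object, nsim = 1000, seed = NULL,
                                stimulus = NULL, s0 = NULL,
                                mode = c("parallel", "asynchronous"), ...) {
  mode <- match.arg(mode)
  net <- object
  if (!is.null(seed)) set.seed(seed)
  x <- NULL
  if (!is.null(stimulus))
    x <- if (inherits(stimulus, "stim_traj")) stimulus$x else as.matrix(stimulus)
  T <- if (is.null(x)) nsim else ncol(x)
  N <- net$N
  if (is.null(s0)) s0 <- ifelse(stats::runif(N) < 0.5, 1, -1)
  stopifnot(length(s0) == N, all(s0 == 1 | s0 == -1))
  s <- matrix(0L, N, max(T, 1))
  s[, 1] <- s0
  if (T <= 1) return(s[, seq_len(max(T, 1)), drop = FALSE])
  b2 <- 2 * net$beta
  u <- matrix(stats::runif(N * (T - 1)), N, T - 1)
  if (mode == "parallel") {
    for (t in seq_len(T - 1)) {
      H <- net$J %*% s[, t] + net$bias
      if (!is.null(x)) H <- H + net$Phi %*% x[, t]
      s[, t + 1] <- ifelse(u[, t] < stats::plogis(b2 * H), 1, -1)
    }
  } else {
    cur <- s0
    sites <- matrix(sample.int(N, N * (T - 1), replace = TRUE), N, T - 1)
    for (t in seq_len(T - 1)) {
      for (k in seq_len(N)) {
        i <- sites[k, t]
        H <- sum(net$J[i, ] * cur) + net$bias[i]
        if (!is.null(x)) H <- H + sum(net$Phi[i, ] * x[, t])
        cur[i] <- if (stats::runif(1) < stats::plogis(b2 * H)) 1 else -1
      }
      s[, t + 1] <- cur
    }
  }
  s
}

# numerically stable log(2 cosh(z))
log2cosh <- function(z) abs(z) + log1p(exp(-2 * abs(z)))

#' Exact one-step transition log-probability
#'
#' \eqn{\log P(s_{t+1}|s_t) = \sum_i [\beta s_{t+1,i} H_i -
#' \log 2\cosh(\beta H_i)]}; exponentials over all \eqn{2^N} successors sum
#' to one.
#'
#' @inheritParams compute_field
#' @param s_next successor spin vector.
#' @return Log probability (nats).
#' @export
transition_logprob <- function(net, x_t, s_t, s_next) {
  H <- compute_field(net, x_t, s_t)
  stopifnot(length(s_next) == length(H), all(s_next == 1 | s_next == -1))
  z <- net$beta * H
  sum(s_next * z - log2cosh(z))
}

# all 2^N spin states as an N x 2^N matrix of +/-1 (enumeration oracle
# support; meant for N <= 12)
enumerate_states <- function(N) {
  stopifnot(N <= 14)
  M <- matrix(-1L, N, 2^N)
  for (i in seq_len(N))
    M[i, ] <- rep(rep(c(-1L, 1L), each = 2^(i - 1)), length.out = 2^N)
  M
}
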