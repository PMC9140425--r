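#' Build an encoder/decoder codec
#'
#' The codec holds the random projection \eqn{\Phi \in R^{N \times d}} shared
#' by the linear decoder \eqn{\hat x = \Phi^T r} and the network's input
#' drive, together with the decoding covariance \eqn{\Sigma} (identity by
#' default) and the activity-prior precision \eqn{\Omega} (identity by
#' default, i.e. an uncorrelated empirical prior).
#'
#' @param N network size (number of neurons).
#' @param d stimulus dimension.
#' @param seed integer seed for the Gaussian projection, or \code{NULL}.
#' @param Sigma decoding covariance (\code{d x d}, symmetric positive
#'   definite); default identity.
#' @param Omega activity-prior precision (\code{N x N}, symmetric); default
#'   identity.
#' @return An object of class \code{"codec"}.
#' @export
make_codec <- function(N, d, seed = NULL, Sigma = NULL, Omega = NULL) {
  stopifnot(N >= 1, d >= 1)
  if (!is.null(seed)) set.seed(seed)
  Phi <- matrix(stats::rnorm(N * d), N, d)
  if (is.null(Sigma)) Sigma <- diag(1, d, d)
  if (is.null(Omega)) Omega <- diag(1, N, N)
  stopifnot(all(dim(Sigma) == d), all(dim(Omega) == N))
  if (!isTRUE(all.equal(Sigma, t(Sigma))))
    stop("Sigma must be symmetric")
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("Sigma must be positive definite")
  if (!isTRUE(all.equal(Omega, t(Omega))))
    stop("Omega must be symmetric")
  structure(list(Phi = Phi, Sigma = Sigma, Omega = Omega, N = N, d = d,
                 seed = seed),
            class = "codec")
}

#' @export
print.codec <- function(x, ...) {
  cat("Codec: N =", x$N, "neurons, d =", x$d, "stimulus dimension(s)\n")
  invisible(x)
}

#' Posterior-mode encoding rate
#'
#' The mode of the Gaussian response posterior under the linear-decoding
#' model, \eqn{\lambda = \Phi \Sigma^{-1} x}: the rate drive each neuron
#' receives so that the population optimally encodes the stimulus. Linear in
#' \code{x}.
#'
#' @param codec a [make_codec()] object.
#' @param x stimulus: length-\code{d} vector or \code{d x T} matrix.
#' @return Rate vector (length \code{N}) or matrix (\code{N x T}).
#' @export
posterior_rate <- function(codec, x) {
  stopifnot(inherits(codec, "codec"))
  if (inherits(x, "stim_traj")) x <- x$x
  xm <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  if (nrow(xm) != codec$d)
    stop("stimulus has ", nrow(xm), " rows; codec expects d = ", codec$d)
  rc <- rcond(codec$Sigma)
  if (!is.finite(rc) || rc < 1e-12)
    stop("Sigma is (numerically) singular; cannot form the posterior mode")
  lam <- codec$Phi %*% solve(codec$Sigma, xm)
  if (is.matrix(x)) lam else drop(lam)
}

#' Sample a Bernoulli spike raster from encoding rates
#'
#' Each time bin is drawn independently with spike probability given by the
#' logistic of the rate times the bin width; a spike maps to \code{+1} and a
#' silence to \code{-1}, so the target code feeds the \eqn{\pm1} kinetic
#' Ising machinery directly. The default (increasing) convention is
#' \eqn{p = 1/(1 + e^{-\lambda dt})}, under which a stronger positive drive
#' raises the spike probability; \code{decreasing = TRUE} flips the sign in
#' the exponent.
#'
#' @param rates rate matrix (\code{N x T}) or vector.
#' @param dt bin width (time, \code{> 0}).
#' @param seed integer seed or \code{NULL}.
#' @param decreasing use the sign convention under which probability
#'   decreases with the rate.
#' @return An object of class \code{"target_code"} with fields \code{rates},
#'   \code{spikes} (entries exactly \eqn{\pm1}), \code{dt}, \code{seed}.
#' @export
sample_spikes <- function(rates, dt, seed = NULL, decreasing = FALSE) {
  stopifnot(dt > 0)
  if (!is.null(seed)) set.seed(seed)
  rm_ <- if (is.matrix(rates)) rates else matrix(rates, nrow = 1)
  p <- stats::plogis(if (decreasing) -rm_ * dt else rm_ * dt)
  u <- matrix(stats::runif(length(p)), nrow(p), ncol(p))
  spikes <- ifelse(u < p, 1, -1)
  structure(list(rates = rm_, spikes = spikes, dt = dt, seed = seed),
            class = "target_code")
}

#' @export
print.target_code <- function(x, ...) {
  cat("Target code:", nrow(x$spikes), "neurons x", ncol(x$spikes),
      "bins, dt =", x$dt, "\n")
  cat("  mean spike probability:",
      signif(mean(x$spikes > 0), 3), "\n")
  invisible(x)
}

#' Variational lower bound on stimulus information
#'
#' Computes \eqn{H(x) - \langle -\log P(x|s) \rangle}, the variational
#' (Barber-Agakov) lower bound on the mutual information between stimulus and
#' response: \eqn{H(x)} is the Gaussian entropy of the empirical stimulus
#' covariance and \eqn{P(x|s)} the Gaussian linear decoder
#' \eqn{N(\Phi^T s, \Sigma)}. For jointly Gaussian stimulus/response pairs
#' the bound never exceeds the true mutual information.
#'
#' @param codec a [make_codec()] object.
#' @param traj stimulus trajectory (\code{"stim_traj"} or \code{d x T}
#'   matrix).
#' @param code response: a \code{"target_code"} (its spikes are used) or a
#'   plain \code{N x T} response matrix.
#' @param bits return bits/step instead of nats/step.
#' @return Scalar lower bound (nats/step, or bits/step).
#' @export
info_lower_bound <- function(codec, traj, code, bits = FALSE) {
  stopifnot(inherits(codec, "codec"))
  x <- if (inherits(traj, "stim_traj")) traj$x else as.matrix(traj)
  r <- if (inherits(code, "target_code")) code$spikes else as.matrix(code)
  if (ncol(x) != ncol(r)) stop("stimulus and code must share T")
  d <- nrow(x)
  Cx <- stats::cov(t(x))
  detC <- det(as.matrix(Cx))
  if (!is.finite(detC) || detC <= 0)
    stop("degenerate empirical stimulus covariance; entropy undefined")
  Hx <- 0.5 * (d * log(2 * pi * exp(1)) + log(detC))
  xhat <- t(codec$Phi) %*% r
  U <- chol(codec$Sigma)
  err <- backsolve(U, x - xhat, transpose = TRUE)
  nll <- 0.5 * d * log(2 * pi) + sum(log(diag(U))) +
    0.5 * mean(colSums(err^2))
  bound <- Hx - nll
  if (bits) bound / log(2) else bound
}
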