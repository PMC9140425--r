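#' Spin correlation statistics of a raster
#'
#' Means, equal-time and one-step-delayed correlation matrices, in both raw
#' (\eqn{C_{ij} = \langle s_i(t) s_j(t)\rangle},
#' \eqn{B_{ij} = \langle s_i(t+1) s_j(t)\rangle}) and connected
#' (mean-subtracted) form, together with the diagonal response factor
#' \eqn{a_i = \beta(1 - m_i^2)} used by the mean-field inversion.
#'
#' @param raster spin raster (\code{N x T}, entries \eqn{\pm1}).
#' @param beta inverse temperature used to form \code{A}.
#' @return A list of class \code{"kising_stats"}: \code{m}, \code{C},
#'   \code{B} (raw), \code{C_conn}, \code{B_conn} (connected), \code{A}
#'   (diagonal matrix), \code{frozen} (indices with \eqn{|m_i| = 1}),
#'   \code{T}.
#' @export
correlation_stats <- function(raster, beta = 0.5) {
  s <- as.matrix(raster)
  N <- nrow(s); T <- ncol(s)
  stopifnot(T >= 2, all(s == 1 | s == -1))
  m <- rowMeans(s)
  C <- tcrossprod(s) / T
  S0 <- s[, -T, drop = FALSE]
  S1 <- s[, -1, drop = FALSE]
  B <- tcrossprod(S1, S0) / (T - 1)
  C_conn <- C - tcrossprod(m)
  B_conn <- B - tcrossprod(rowMeans(S1), rowMeans(S0))
  frozen <- which(abs(m) == 1)
  if (length(frozen))
    warning("frozen neuron(s) ", paste(frozen, collapse = ", "),
            " (|m| = 1): mean-field inversion would be singular")
  structure(list(m = m, C = C, B = B, C_conn = C_conn, B_conn = B_conn,
                 A = diag(beta * (1 - m^2), N, N), beta = beta,
                 frozen = frozen, T = T),
            class = "kising_stats")
}

#' Fit a kinetic Ising network to a spike raster
#'
#' Reconstructs the coupling matrix (and static field) that best explain an
#' observed \eqn{\pm1} raster under the parallel Glauber kernel, by
#' maximum-likelihood gradient ascent on the spin-history objective
#' \deqn{L = \sum_i \sum_t [\beta s_i(t+1) H_i(t) - \log 2\cosh(\beta H_i(t))]}
#' (\code{method = "gradient"}) or by the closed-form naive mean-field
#' inversion \eqn{\hat J = B (A C)^{-1}} (\code{method = "meanfield"}).
#'
#' When a stimulus and projection are supplied, the stimulus drive
#' \eqn{\Phi x(t)} is treated as observed data inside the field and only the
#' couplings (and optionally a static bias) are learned; this separation is
#' what later allows the stimulus to be decoded back from the field. The
#' gradient update matches delayed moments,
#' \eqn{\delta J_{ij} \propto \gamma\beta(\langle s_i(t+1) s_j(t)\rangle -
#' \langle \tanh(\beta H_i(t)) s_j(t)\rangle)}, so at a fixed point the
#' model's delayed correlations reproduce the data's.
#'
#' @param raster spin raster (\code{N x T}, entries \eqn{\pm1}).
#' @param beta inverse temperature of the fitted kernel.
#' @param method \code{"gradient"} (default) or \code{"meanfield"}.
#' @param stimulus optional \code{"stim_traj"} or \code{d x T} matrix of
#'   observed input.
#' @param Phi input projection (\code{N x d}); required with
#'   \code{stimulus}.
#' @param gamma learning rate for the gradient method.
#' @param iters maximum gradient iterations.
#' @param tol early-stopping threshold on the objective improvement per
#'   iteration.
#' @param learn_couplings learn \code{J}? (\code{FALSE} fixes \code{J} at
#'   \code{J0}, e.g. the zero matrix of an independent population).
#' @param learn_bias learn a static per-neuron field?
#' @param J0 initial couplings; default is the ridge-regularized inverse
#'   covariance of the raster (ridge \code{1e-3}), or the zero matrix when
#'   \code{learn_couplings = FALSE}.
#' @param connected mean-field method only: use connected (mean-subtracted)
#'   correlations (default) rather than the literal raw moments.
#' @param ridge mean-field method only: ridge added to \code{A C} before
#'   inversion (default 0).
#' @param seed integer seed or \code{NULL} (the gradient fit itself is
#'   deterministic; the seed is recorded for provenance).
#' @return An object of class \code{c("kising_fit", "kising_net")}: the
#'   fitted network plus \code{method}, \code{loglik_trace}, \code{gamma},
#'   \code{iters} (iterations actually run), \code{stats} (the
#'   [correlation_stats()] of the training raster) and the training
#'   dimensions. Standard methods are available: [coef()], [logLik()],
#'   [summary()], [simulate()], [predict.kising_fit()],
#'   [residuals.kising_fit()].
#' @examples
#' set.seed(1)
#' J <- matrix(rnorm(25, sd = 1 / sqrt(5)), 5, 5)
#' net <- kinetic_ising_net(J, beta = 0.5)
#' s <- simulate(net, nsim = 2000, seed = 2)
#' fit <- fit_kinetic_ising(s, beta = 0.5, iters = 200)
#' cor(as.vector(coef(fit)), as.vector(J))
#' @export
fit_kinetic_ising <- function(raster, beta = 0.5,
                              method = c("gradient", "meanfield"),
                              stimulus = NULL, Phi = NULL,
                              gamma = 0.1, iters = 1000, tol = 1e-8,
                              learn_couplings = TRUE, learn_bias = TRUE,
                              J0 = NULL, connected = TRUE, ridge = 0,
                              seed = NULL) {
  method <- match.arg(method)
  s <- as.matrix(raster)
  if (inherits(raster, "target_code")) s <- raster$spikes
  N <- nrow(s); T <- ncol(s)
  stopifnot(T >= 2, all(s == 1 | s == -1), beta >= 0, gamma > 0)
  cs <- correlation_stats(s, beta)
  x <- NULL
  if (!is.null(stimulus)) {
    x <- if (inherits(stimulus, "stim_traj")) stimulus$x else as.matrix(stimulus)
    if (is.null(Phi)) stop("'Phi' is required when a stimulus is supplied")
    Phi <- as.matrix(Phi)
    stopifnot(nrow(Phi) == N, ncol(Phi) == nrow(x), ncol(x) == T)
  }
  if (method == "meanfield") {
    fit <- meanfield_couplings(cs, beta, connected = connected, ridge = ridge)
    net <- kinetic_ising_net(fit$J, beta = beta, Phi = Phi, bias = fit$bias)
    net$method <- "meanfield"
    net$loglik_trace <- loglik_raster(s, net, x)
    net$gamma <- NA_real_
    net$iters <- 0L
    net$stats <- cs
    net$seed <- seed
    class(net) <- c("kising_fit", class(net))
    return(net)
  }
  # gradient ascent on the spin-history likelihood
  if (is.null(J0)) {
    J0 <- if (learn_couplings)
      solve(cs$C_conn + diag(1e-3, N, N)) else matrix(0, N, N)
  }
  J <- as.matrix(J0)
  stopifnot(all(dim(J) == N))
  bias <- numeric(N)
  S0 <- s[, -T, drop = FALSE]
  S1 <- s[, -1, drop = FALSE]
  Hfix <- if (is.null(x)) 0 else Phi %*% x[, -T, drop = FALSE]
  B_raw <- tcrossprod(S1, S0) / (T - 1)
  m1 <- rowMeans(S1)
  trace <- numeric(iters)
  it <- 0L
  for (k in seq_len(iters)) {
    H <- J %*% S0 + bias + Hfix
    z <- beta * H
    trace[k] <- sum(S1 * z) - sum(log2cosh(z))
    if (!is.finite(trace[k]))
      stop("objective diverged (non-finite) at iteration ", k,
           "; reduce gamma")
    tb <- tanh(z)
    if (learn_couplings)
      J <- J + gamma * beta * (B_raw - tcrossprod(tb, S0) / (T - 1))
    if (learn_bias)
      bias <- bias + gamma * beta * (m1 - rowMeans(tb))
    it <- k
    if (k > 1 && abs(trace[k] - trace[k - 1]) < tol) break
  }
  net <- kinetic_ising_net(J, beta = beta, Phi = Phi, bias = bias)
  net$method <- "gradient"
  net$loglik_trace <- trace[seq_len(it)]
  net$gamma <- gamma
  net$iters <- it
  net$stats <- cs
  net$seed <- seed
  class(net) <- c("kising_fit", class(net))
  net
}

# closed-form naive mean-field inversion J = B (A C)^{-1}
meanfield_couplings <- function(cs, beta, connected = TRUE, ridge = 0) {
  if (length(cs$frozen))
    stop("frozen neuron(s) make A C singular; drop them or add data")
  Cm <- if (connected) cs$C_conn else cs$C
  Bm <- if (connected) cs$B_conn else cs$B
  AC <- cs$A %*% Cm + diag(ridge, nrow(Cm))
  rc <- rcond(AC)
  if (!is.finite(rc) || rc < 1e-12)
    stop("A C is numerically singular; try the 'ridge' argument")
  J <- Bm %*% solve(AC)
  # static field consistent with the mean activity under the naive
  # mean-field self-consistency m = tanh(beta(bias + J m))
  mc <- pmin(pmax(cs$m, -1 + 1e-12), 1 - 1e-12)
  bias <- drop(atanh(mc) / beta - J %*% cs$m)
  list(J = J, bias = bias)
}

#' Naive mean-field coupling estimate
#'
#' Convenience wrapper around [fit_kinetic_ising()] with
#' \code{method = "meanfield"}: the closed-form estimate
#' \eqn{\hat J_{MF} = B (A C)^{-1}} from delayed and equal-time
#' correlations.
#'
#' @inheritParams fit_kinetic_ising
#' @return A \code{"kising_fit"}.
#' @export
fit_meanfield <- function(raster, beta = 0.5, connected = TRUE, ridge = 0) {
  fit_kinetic_ising(raster, beta = beta, method = "meanfield",
                    connected = connected, ridge = ridge)
}

# total spin-history log-likelihood of a raster under a network
loglik_raster <- function(s, net, x = NULL) {
  T <- ncol(s)
  S0 <- s[, -T, drop = FALSE]
  S1 <- s[, -1, drop = FALSE]
  H <- net$J %*% S0 + net$bias
  if (!is.null(x)) H <- H + net$Phi %*% x[, -T, drop = FALSE]
  z <- net$beta * H
  sum(S1 * z) - sum(log2cosh(z))
}

#' Log-likelihood of a raster under a kinetic Ising network
#'
#' Sum of the exact one-step transition log-probabilities along the
#' trajectory — the objective maximized by the gradient fit.
#'
#' @param raster spin raster (\code{N x T}).
#' @param net a [kinetic_ising_net()] or fitted \code{"kising_fit"}.
#' @param stimulus optional stimulus (\code{"stim_traj"} or matrix); uses the
#'   network's \code{Phi}.
#' @return Log-likelihood in nats.
#' @export
kising_loglik <- function(raster, net, stimulus = NULL) {
  s <- as.matrix(raster)
  stopifnot(inherits(net, "kising_net"), nrow(s) == net$N,
            all(s == 1 | s == -1))
  x <- NULL
  if (!is.null(stimulus)) {
    x <- if (inherits(stimulus, "stim_traj")) stimulus$x else as.matrix(stimulus)
    stopifnot(ncol(x) == ncol(s))
  }
  loglik_raster(s, net, x)
}

#' @export
coef.kising_fit <- function(object, ...) object$J

#' @export
logLik.kising_fit <- function(object, ...) {
  ll <- object$loglik_trace[length(object$loglik_trace)]
  attr(ll, "df") <- object$N^2 + object$N
  class(ll) <- "logLik"
  ll
}

#' @export
print.kising_fit <- function(x, ...) {
  cat("Kinetic Ising fit (", x$method, " method)\n", sep = "")
  cat("  N =", x$N, ", beta =", x$beta, ", T =", x$stats$T, "\n")
  if (x$method == "gradient")
    cat("  iterations:", x$iters, " (gamma =", x$gamma, ")\n")
  cat("  log-likelihood:", format(x$loglik_trace[length(x$loglik_trace)]),
      "\n")
  cat("  asymmetry eta =", signif(asymmetry(x$J), 3), "\n")
  invisible(x)
}

#' @export
summary.kising_fit <- function(object, ...) {
  out <- list(
    method = object$method, N = object$N, beta = object$beta,
    T = object$stats$T, iters = object$iters,
    loglik = object$loglik_trace[length(object$loglik_trace)],
    eta = asymmetry(object$J),
    ep_pairwise = entropy_production_pairwise(object$J, object$stats$B),
    coupling_sd = stats::sd(object$J),
    mean_activity = mean(object$stats$m))
  class(out) <- "summary.kising_fit"
  out
}

#' @export
print.summary.kising_fit <- function(x, ...) {
  cat("Kinetic Ising fit summary\n")
  cat("  method:", x$method, "  N:", x$N, "  beta:", x$beta,
      "  T:", x$T, "\n")
  cat("  log-likelihood:", format(x$loglik), "\n")
  cat("  asymmetry eta:", signif(x$eta, 4), "\n")
  cat("  pairwise entropy production (training raster):",
      signif(x$ep_pairwise, 4), "nats/step\n")
  cat("  coupling sd:", signif(x$coupling_sd, 4),
      "  mean activity:", signif(x$mean_activity, 4), "\n")
  invisible(x)
}

#' Moment-matching residuals of a kinetic Ising fit
#'
#' The gradient of the likelihood at the fitted parameters, i.e. the mismatch
#' \eqn{\langle s_i(t+1) s_j(t)\rangle - \langle \tanh(\beta H_i(t))
#' s_j(t)\rangle} recomputed on a raster; near zero at a converged fit.
#'
#' @param object a \code{"kising_fit"}.
#' @param raster evaluation raster; default the training statistics cannot be
#'   reused, so a raster must be supplied together with any stimulus.
#' @param stimulus optional stimulus matching the raster.
#' @param ... unused.
#' @return \code{N x N} residual matrix (plus a \code{"bias"} attribute with
#'   the field residual).
#' @export
residuals.kising_fit <- function(object, raster, stimulus = NULL, ...) {
  s <- as.matrix(raster)
  T <- ncol(s)
  S0 <- s[, -T, drop = FALSE]
  S1 <- s[, -1, drop = FALSE]
  H <- object$J %*% S0 + object$bias
  if (!is.null(stimulus)) {
    x <- if (inherits(stimulus, "stim_traj")) stimulus$x else as.matrix(stimulus)
    H <- H + object$Phi %*% x[, -T, drop = FALSE]
  }
  tb <- tanh(object$beta * H)
  res <- tcrossprod(S1, S0) / (T - 1) - tcrossprod(tb, S0) / (T - 1)
  attr(res, "bias") <- rowMeans(S1) - rowMeans(tb)
  res
}

#' @export
plot.kising_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  if (x$method == "gradient" && length(x$loglik_trace) > 1)
    graphics::plot(x$loglik_trace, type = "l", xlab = "iteration",
                   ylab = "log-likelihood", main = "objective")
  else
    graphics::plot.new()
  graphics::image(t(x$J)[, rev(seq_len(x$N))], axes = FALSE,
                  main = "couplings J", col = grDevices::hcl.colors(64))
  invisible(x)
}
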