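#' Specify a linear stochastic stimulus model
#'
#' Defines the multivariate Ornstein-Uhlenbeck family used as dynamic input:
#' \deqn{dx/dt = \tilde M x + c(t) + \xi, \qquad \xi \sim N(0, \Sigma_x)}
#' The user supplies decay-rate magnitudes for the diagonal of the drift and an
#' optional target cross-correlation between channels; the effective drift is
#' \eqn{\tilde M = -\mathrm{diag}(decay) + offdiag}, so printed decay values are
#' interpreted as inverse autocorrelation times of a stationary process.
#'
#' @param d input dimension.
#' @param decay decay-rate magnitude(s) for the drift diagonal (1/time);
#'   recycled to length \code{d}. The effective drift diagonal is
#'   \code{-decay}.
#' @param cross target stationary cross-correlation between channels. With
#'   the default \code{cross_mode = "directed"} the correlation is realized
#'   by a feed-forward drift coupling (channel \eqn{i} drives channel
#'   \eqn{i+1}): correlated channels are then also temporally irreversible,
#'   the way shared dynamic sources make natural stimuli directional. The
#'   directed parameterization reaches correlations up to
#'   \eqn{1/\sqrt{2} \approx 0.707} (exact for \code{d = 2});
#'   \code{cross_mode = "symmetric"} uses equal off-diagonal couplings
#'   (time-reversible, correlation up to 1 for \code{d = 2}).
#' @param cross_mode how the cross-correlation is realized (see
#'   \code{cross}).
#' @param noise noise intensity: scalar (diagonal \code{noise * I}) or a
#'   \code{d x d} covariance-rate matrix \eqn{\Sigma_x} (signal^2/time).
#' @param dt integration step (time).
#' @param bounds length-2 numeric \code{c(lo, hi)} output range used when a
#'   trajectory is bounded, or \code{NULL} for unbounded output.
#' @param control optional control signal: a \code{d x T} matrix (or a vector
#'   for \code{d = 1}) added to the drift at each step.
#'
#' @return An object of class \code{"stim_model"}.
#' @seealso [simulate_linear()], [simulate_bistable()]
#' @export
stimulus_model <- function(d = 3, decay = 0.5, cross = 0, noise = 0.1,
                           dt = 0.1, bounds = c(-5, 5), control = NULL,
                           cross_mode = c("directed", "symmetric")) {
  stopifnot(d >= 1, dt > 0)
  cross_mode <- match.arg(cross_mode)
  decay <- rep_len(decay, d)
  if (cross < 0 || cross >= 1)
    stop("'cross' must lie in [0, 1)")
  M <- -diag(decay, d, d)
  if (d > 1 && cross > 0) {
    if (cross_mode == "directed") {
      if (cross >= 1 / sqrt(2))
        stop("directed cross-coupling reaches correlations < 0.707; ",
             "use cross_mode = \"symmetric\" for stronger correlation")
      u <- cross / sqrt(1 - 2 * cross^2)
      for (i in seq_len(d - 1))
        M[i + 1, i] <- u * 2 * decay[1L]
    } else {
      M[row(M) != col(M)] <- cross * decay[1L]
    }
  }
  if (is.matrix(noise)) {
    Sigma_x <- noise
  } else {
    stopifnot(length(noise) == 1L, noise >= 0)
    Sigma_x <- diag(noise, d, d)
  }
  if (!isTRUE(all.equal(Sigma_x, t(Sigma_x))))
    stop("noise covariance must be symmetric")
  ev <- eigen(Sigma_x, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1))
    stop("noise covariance must be positive semidefinite")
  if (!is.null(control)) {
    if (!is.matrix(control)) control <- matrix(control, nrow = d)
    if (nrow(control) != d) stop("control must have d rows")
  }
  if (!is.null(bounds)) {
    stopifnot(length(bounds) == 2L, bounds[1] < bounds[2])
  }
  structure(list(d = d, M = M, Sigma_x = Sigma_x, control = control,
                 dt = dt, bounds = bounds),
            class = "stim_model")
}

#' @export
print.stim_model <- function(x, ...) {
  cat("Linear stochastic stimulus model\n")
  cat("  dimension d =", x$d, ", dt =", x$dt, "\n")
  cat("  drift eigenvalues:",
      paste(signif(Re(eigen(x$M, only.values = TRUE)$values), 3),
            collapse = ", "), "\n")
  if (!is.null(x$bounds))
    cat("  bounds: [", x$bounds[1], ",", x$bounds[2], "]\n")
  invisible(x)
}

# Affine rescale of each channel into [lo, hi]. For symmetric bounds the map
# is a pure positive scaling (x -> x * hi / max|x|), which preserves the sign
# pattern; for asymmetric bounds a min/max affine map is used.
bound_trajectory <- function(x, lo, hi) {
  for (i in seq_len(nrow(x))) {
    r <- range(x[i, ])
    if (r[1] == r[2]) next
    if (isTRUE(all.equal(lo, -hi))) {
      x[i, ] <- x[i, ] * (hi / max(abs(x[i, ])))
    } else {
      x[i, ] <- lo + (x[i, ] - r[1]) * (hi - lo) / (r[2] - r[1])
    }
  }
  x
}

new_stim_traj <- function(x, dt, seed, bounds, model = NULL) {
  traj <- structure(list(x = x, dt = dt, seed = seed, bounds = bounds,
                         model = model, stats = NULL),
                    class = "stim_traj")
  traj$stats <- stimulus_statistics(traj)
  traj
}

#' @export
print.stim_traj <- function(x, ...) {
  cat("Stimulus trajectory:", nrow(x$x), "channel(s) x", ncol(x$x),
      "steps, dt =", x$dt, "\n")
  s <- x$stats
  cat("  sigma_cross =", signif(s$sigma_cross, 3),
      " alpha_scale =", signif(s$alpha_scale, 3),
      " p_zero =", signif(s$p_zero, 3), "\n")
  invisible(x)
}

#' Simulate a linear stochastic (Ornstein-Uhlenbeck) stimulus
#'
#' Euler-Maruyama integration of the model's stochastic differential equation.
#' Without a control signal the effective drift must be stable (all eigenvalue
#' real parts non-positive); an unstable drift raises an error naming the
#' offending eigenvalue. When the model carries bounds and \code{bound = TRUE},
#' each channel is affinely rescaled into them after integration (see
#' \code{bounds} in [stimulus_model()]); bounding is a whole-trajectory rescale,
#' not per-step clipping, so it does not distort autocorrelation.
#'
#' @param model a [stimulus_model()].
#' @param T number of time steps (\code{>= 2}).
#' @param seed integer seed, or \code{NULL} to use the current RNG state.
#' @param x0 initial state (length \code{d}); default zero.
#' @param bound apply the model's bounds (default \code{TRUE} when the model
#'   has bounds).
#' @return An object of class \code{"stim_traj"} with fields \code{x}
#'   (\code{d x T} matrix), \code{dt}, \code{seed} and summary \code{stats}
#'   (see [stimulus_statistics()]).
#' @examples
#' m <- stimulus_model(d = 1, decay = 0.5, noise = 0.1, bounds = NULL)
#' tr <- simulate_linear(m, T = 1000, seed = 1)
#' var(tr$x[1, ])  # approaches 0.1 / (2 * 0.5) for long runs
#' @export
simulate_linear <- function(model, T, seed = NULL, x0 = NULL,
                            bound = !is.null(model$bounds)) {
  stopifnot(inherits(model, "stim_model"), T >= 2)
  d <- model$d
  if (is.null(model$control)) {
    ev <- eigen(model$M, only.values = TRUE)$values
    bad <- which(Re(ev) > 1e-12)
    if (length(bad))
      stop("unstable drift without control: eigenvalue ",
           format(ev[bad[which.max(Re(ev[bad]))]]),
           " has positive real part; trajectory would diverge")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(x0)) x0 <- numeric(d)
  stopifnot(length(x0) == d)
  dt <- model$dt
  L <- NULL
  if (any(model$Sigma_x != 0)) {
    es <- eigen(model$Sigma_x, symmetric = TRUE)
    L <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), d, d)
  }
  ctrl <- model$control
  x <- matrix(0, d, T)
  x[, 1] <- x0
  noise <- if (is.null(L)) NULL else L %*% matrix(stats::rnorm(d * (T - 1)), d) * sqrt(dt)
  for (t in seq_len(T - 1)) {
    drift <- model$M %*% x[, t]
    if (!is.null(ctrl)) drift <- drift + ctrl[, min(t, ncol(ctrl))]
    x[, t + 1] <- x[, t] + dt * drift + (if (is.null(noise)) 0 else noise[, t])
  }
  if (!all(is.finite(x)))
    stop("trajectory diverged (non-finite values); check drift stability")
  bounds <- if (bound && !is.null(model$bounds)) model$bounds else NULL
  if (!is.null(bounds)) x <- bound_trajectory(x, bounds[1], bounds[2])
  new_stim_traj(x, dt, seed, bounds, model)
}

#' Simulate a bistable (two-state telegraph) stimulus
#'
#' A one-dimensional control signal switches between \code{+separation/2} and
#' \code{-separation/2} as an exact telegraph process (exponential waiting
#' times with rate \code{switch_rate}); the output relaxes toward the active
#' state with additive noise, so its marginal is a mixture of two modes whose
#' overlap is controlled by \code{separation / noise_sd}. The fraction of
#' probability mass near zero (\code{p_zero} in the trajectory's stats)
#' measures the overlap of the two states.
#'
#' @param separation distance between the two state means (signal units,
#'   \code{>= 0}).
#' @param noise_sd stationary standard deviation of fluctuations about the
#'   active state (signal units, \code{>= 0}).
#' @param switch_rate telegraph switching rate (1/time), in \code{(0, 1/dt)}.
#' @param T number of time steps.
#' @param seed integer seed or \code{NULL}.
#' @param dt integration step.
#' @param relax relaxation rate toward the active state (1/time).
#' @param bounds output range applied by affine rescale, or \code{NULL}.
#' @return A \code{"stim_traj"} (with \code{d = 1}).
#' @export
simulate_bistable <- function(separation, noise_sd, switch_rate, T,
                              seed = NULL, dt = 0.1, relax = 0.5,
                              bounds = c(-5, 5)) {
  if (separation < 0) stop("'separation' must be >= 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (switch_rate <= 0 || switch_rate >= 1 / dt)
    stop("'switch_rate' must lie in (0, 1/dt)")
  if (!is.null(seed)) set.seed(seed)
  total_time <- T * dt
  # exact telegraph: exponential waiting times between switches
  times <- 0
  while (sum(times) < total_time)
    times <- c(times, stats::rexp(1, rate = switch_rate))
  switch_at <- cumsum(times)[-1]
  state <- rep(1, T)
  sgn <- if (stats::runif(1) < 0.5) 1 else -1
  tgrid <- (seq_len(T) - 1) * dt
  state <- sgn * (-1)^(findInterval(tgrid, switch_at))
  c_t <- state * separation / 2
  # OU relaxation toward the active state; stationary sd about the mean is
  # noise_sd (noise intensity 2 * relax * noise_sd^2)
  sig <- noise_sd * sqrt(2 * relax)
  x <- numeric(T)
  x[1] <- c_t[1] + stats::rnorm(1) * noise_sd
  z <- stats::rnorm(T - 1) * sig * sqrt(dt)
  for (t in seq_len(T - 1))
    x[t + 1] <- x[t] + dt * relax * (c_t[t] - x[t]) + z[t]
  x <- matrix(x, 1, T)
  if (!is.null(bounds)) x <- bound_trajectory(x, bounds[1], bounds[2])
  traj <- new_stim_traj(x, dt, seed, bounds)
  traj$control_state <- c_t
  traj
}

#' Summary statistics of a stimulus trajectory
#'
#' Pure function of the sample path. Returns the mean pairwise correlation of
#' channels (\code{sigma_cross}), the exponential decay rate fitted to the
#' mean normalized autocorrelation (\code{alpha_scale}, in 1/time), and the
#' probability mass near zero (\code{p_zero}, the histogram mass in a central
#' bin of width 5\% of the output range). Constant channels make the
#' correlation undefined; they are reported as \code{NA} with a warning,
#' never as zero.
#'
#' @param traj a \code{"stim_traj"} or a plain numeric matrix (channels in
#'   rows) with attribute-free default \code{dt = 1}.
#' @param max_lag maximum lag (steps) used in the autocorrelation fit.
#' @return A list with \code{sigma_cross}, \code{alpha_scale}, \code{p_zero},
#'   \code{p_zero_binwidth} and \code{constant_channels}.
#' @export
stimulus_statistics <- function(traj, max_lag = 200L) {
  if (inherits(traj, "stim_traj")) {
    x <- traj$x; dt <- traj$dt; bounds <- traj$bounds
  } else {
    x <- as.matrix(traj); dt <- 1; bounds <- NULL
  }
  d <- nrow(x); T <- ncol(x)
  sds <- apply(x, 1, stats::sd)
  const <- unname(which(sds == 0))
  if (length(const))
    warning("constant channel(s) ", paste(const, collapse = ", "),
            ": correlation undefined, reported as NA")
  sigma_cross <- NA_real_
  if (d >= 2) {
    ok <- setdiff(seq_len(d), const)
    if (length(ok) >= 2) {
      C <- stats::cor(t(x[ok, , drop = FALSE]))
      sigma_cross <- mean(C[upper.tri(C)])
    }
  }
  # mean autocorrelation across non-constant channels, exponential fit
  alpha_scale <- NA_real_
  ok <- setdiff(seq_len(d), const)
  if (length(ok) && T >= 100) {
    L <- min(max_lag, T %/% 5)
    ac <- rowMeans(vapply(ok, function(i)
      stats::acf(x[i, ], lag.max = L, plot = FALSE,
                 demean = TRUE)$acf[-1, 1, 1], numeric(L)))
    lags <- seq_len(L) * dt
    pos <- ac > 0.05
    cutoff <- if (any(!pos)) which(!pos)[1] - 1L else L
    if (cutoff >= 2) {
      fit <- stats::lm(log(ac[1:cutoff]) ~ 0 + lags[1:cutoff])
      alpha_scale <- -unname(stats::coef(fit)[1])
    }
  }
  rng <- if (!is.null(bounds)) bounds else range(x)
  bw <- 0.05 * (rng[2] - rng[1])
  p_zero <- mean(abs(x) <= bw / 2)
  list(sigma_cross = sigma_cross, alpha_scale = alpha_scale,
       p_zero = p_zero, p_zero_binwidth = bw,
       constant_channels = const)
}
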