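#' Linear stimulus decoding
#'
#' Fixed linear readout \eqn{\hat x(t) = \Phi^T r(t)} with \eqn{r} either the
#' raw spins (default) or an exponentially filtered, rate-like version with
#' time constant \code{smooth_tau}.
#'
#' @param codec a [make_codec()] object (or anything carrying \code{Phi}).
#' @param raster spin raster (\code{N x T}, \eqn{\pm1}) or plain response
#'   matrix.
#' @param smooth_tau optional filter time constant (time units); \code{NULL}
#'   decodes instantaneous spins.
#' @param dt time step used by the filter.
#' @return Reconstruction matrix (\code{d x T}).
#' @export
linear_decode <- function(codec, raster, smooth_tau = NULL, dt = 0.1) {
  Phi <- codec$Phi
  r <- as.matrix(raster)
  stopifnot(nrow(r) == nrow(Phi))
  if (!is.null(smooth_tau)) {
    a <- exp(-dt / smooth_tau)
    r <- t(apply(r, 1, function(v) stats::filter(v * (1 - a), a,
                                                 method = "recursive")))
  }
  t(Phi) %*% r
}

#' Field-based stimulus decoding
#'
#' Decodes by inverting the field relation \eqn{\Phi x(t) = H(t) - J s(t) -
#' b}: a per-step least-squares solve with ridge \code{1e-6} on
#' \eqn{\Phi^T\Phi}. The total field is either supplied exactly (\code{H})
#' or estimated from the raster itself: the expected next spin is
#' \eqn{\tanh(\beta H_i(t))}, so a moving-average smoothing of the one-step
#' advanced spins gives \eqn{\hat H = \mathrm{atanh}(\tilde s)/\beta}.
#'
#' @param net a [kinetic_ising_net()] (must carry \code{Phi}).
#' @param raster spin raster (\code{N x T}).
#' @param H optional exact field matrix (\code{N x T-1} or \code{N x T});
#'   when omitted the field is estimated from the raster.
#' @param window odd moving-average width (bins) for field estimation.
#' @return Reconstruction matrix (\code{d x T}); the final column repeats the
#'   previous estimate, since no successor spin constrains it.
#' @export
field_decode <- function(net, raster, H = NULL, window = 9L) {
  stopifnot(inherits(net, "kising_net"))
  if (is.null(net$Phi)) stop("network carries no input projection Phi")
  Phi <- net$Phi
  d <- ncol(Phi); N <- net$N
  if (d > N) stop("underdetermined decode: d = ", d, " > N = ", N,
                  "; use a larger network")
  if (qr(Phi)$rank < d)
    stop("rank-deficient Phi; decoding needs a larger or richer N")
  s <- as.matrix(raster)
  T <- ncol(s)
  if (is.null(H) && net$beta == 0) {
    warning("beta = 0: spins carry no field information; returning zeros")
    return(matrix(0, d, T))
  }
  if (is.null(H)) {
    # estimate tanh(beta H(t)) by smoothing s(t+1) over neighbouring bins
    S1 <- s[, -1, drop = FALSE]
    w <- rep(1 / window, window)
    ms <- t(apply(S1, 1, function(v)
      stats::filter(v, w, method = "convolution", sides = 2,
                    circular = FALSE)))
    ms <- matrix(ms, nrow = N)
    # fill filter edges with the raw one-step mean of available bins
    for (i in seq_len(N)) {
      nas <- which(is.na(ms[i, ]))
      if (length(nas)) ms[i, nas] <- S1[i, nas]
    }
    cap <- 1 - 1 / T
    ms <- pmin(pmax(ms, -cap), cap)
    H <- atanh(ms) / net$beta
  } else {
    H <- as.matrix(H)
  }
  TH <- ncol(H)
  rhs <- H - (net$J %*% s[, seq_len(TH), drop = FALSE] + net$bias)
  G <- crossprod(Phi) + diag(1e-6, d, d)
  xh <- solve(G, crossprod(Phi, rhs))
  if (TH < T) xh <- cbind(xh, xh[, TH])
  xh
}

#' Decoding performance
#'
#' Pearson correlation between reconstruction and truth, computed per
#' stimulus channel and aggregated across dimensions by the arithmetic mean
#' (\code{aggregate = "mean"}, default) or by a single flattened correlation.
#' Invariant to positive affine rescaling of the reconstruction per channel.
#' Zero-variance channels are flagged \code{NA} and excluded from the mean
#' with a warning.
#'
#' @param traj true stimulus (\code{"stim_traj"} or \code{d x T} matrix).
#' @param x_hat reconstruction (\code{d x T}).
#' @param aggregate aggregation across channels.
#' @return List of class \code{"decode_perf"}: \code{D} (scalar in
#'   \eqn{[-1, 1]}), \code{per_dim} (per-channel correlations), \code{x_hat}.
#' @export
decoding_performance <- function(traj, x_hat,
                                 aggregate = c("mean", "flatten")) {
  aggregate <- match.arg(aggregate)
  x <- if (inherits(traj, "stim_traj")) traj$x else as.matrix(traj)
  x_hat <- as.matrix(x_hat)
  stopifnot(all(dim(x) == dim(x_hat)))
  d <- nrow(x)
  per_dim <- vapply(seq_len(d), function(i) {
    if (stats::sd(x[i, ]) == 0 || stats::sd(x_hat[i, ]) == 0)
      return(NA_real_)
    stats::cor(x[i, ], x_hat[i, ])
  }, numeric(1))
  if (anyNA(per_dim))
    warning("zero-variance channel(s) excluded from the decoding score")
  D <- if (aggregate == "mean") {
    mean(per_dim, na.rm = TRUE)
  } else {
    keep <- !is.na(per_dim)
    stats::cor(as.vector(x[keep, , drop = FALSE]),
               as.vector(x_hat[keep, , drop = FALSE]))
  }
  structure(list(D = D, per_dim = per_dim, x_hat = x_hat),
            class = "decode_perf")
}

#' @export
print.decode_perf <- function(x, ...) {
  cat("Decoding performance D =", signif(x$D, 4), "\n")
  cat("  per channel:", paste(signif(x$per_dim, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Decode a stimulus from a fitted kinetic Ising network
#'
#' \code{predict} method dispatching to the linear readout
#' (\code{type = "linear"}, needs the network's \code{Phi}) or the
#' field-inversion decoder (\code{type = "field"}).
#'
#' @param object a \code{"kising_fit"} (or \code{"kising_net"} with
#'   \code{Phi}).
#' @param raster spin raster to decode from.
#' @param type decoder.
#' @param ... passed on to [linear_decode()] or [field_decode()].
#' @return Reconstruction matrix (\code{d x T}).
#' @export
predict.kising_fit <- function(object, raster,
                               type = c("linear", "field"), ...) {
  type <- match.arg(type)
  if (is.null(object$Phi)) stop("fit carries no input projection Phi")
  if (type == "linear") linear_decode(object, raster, ...)
  else field_decode(object, raster, ...)
}
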