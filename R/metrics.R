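#' Connectivity asymmetry ratio
#'
#' \eqn{\eta = \|(J - J^T)/2\|_F / \|(J + J^T)/2\|_F}: the Frobenius-norm
#' ratio of the antisymmetric to the symmetric part of the coupling matrix.
#' Zero iff \code{J} is symmetric; scale invariant
#' (\eqn{\eta(cJ) = \eta(J)}). A purely antisymmetric coupling (zero
#' symmetric part) returns \code{Inf} with a warning.
#'
#' @param J square coupling matrix.
#' @return Non-negative scalar (or \code{Inf}).
#' @export
asymmetry <- function(J) {
  J <- as.matrix(J)
  stopifnot(nrow(J) == ncol(J))
  AS <- (J - t(J)) / 2
  SY <- (J + t(J)) / 2
  nsy <- norm(SY, "F")
  if (nsy == 0) {
    if (norm(AS, "F") == 0) return(0)
    warning("symmetric part is exactly zero (pure rotation coupling)")
    return(Inf)
  }
  norm(AS, "F") / nsy
}

#' Empirical entropy production over pattern space
#'
#' Estimates the stationary irreversibility rate of a spin raster: state
#' probabilities \eqn{\hat P_{ss}} and transition frequencies \eqn{\hat T}
#' over the observed \eqn{2^N} patterns give the flow-weighted average
#' \deqn{EP = \sum_{i,j} \hat P_{ss}(\epsilon_i)\hat T(\epsilon_j|\epsilon_i)
#'   \log\frac{\hat P_{ss}(\epsilon_i)\hat T(\epsilon_j|\epsilon_i)}
#'            {\hat P_{ss}(\epsilon_j)\hat T(\epsilon_i|\epsilon_j)}}
#' which is non-negative by construction and zero iff the observed flows obey
#' detailed balance. Transition pairs whose reverse was never observed carry
#' no finite log-ratio; the default policy excludes them and reports the
#' retained flow mass as \code{coverage}, while
#' \code{policy = "pseudocount"} adds one count to both directions of every
#' observed state pair.
#'
#' @param raster spin raster (\code{N x T}, \eqn{\pm1}) with \code{N <= 14},
#'   or an integer vector of pre-encoded state labels.
#' @param burn_in initial transitions to discard.
#' @param policy handling of one-sided transitions.
#' @param min_coverage below this coverage the estimate is flagged
#'   unreliable (with a warning), never silently returned.
#' @return List: \code{EP} (nats/step), \code{coverage}, \code{n_states}
#'   (distinct patterns seen), \code{n_transitions}, \code{reliable}.
#' @export
entropy_production_empirical <- function(raster, burn_in = 0,
                                         policy = c("exclude", "pseudocount"),
                                         min_coverage = 0.5) {
  policy <- match.arg(policy)
  if (is.matrix(raster)) {
    s <- raster
    N <- nrow(s)
    if (N > 14) stop("pattern-space estimator limited to N <= 14")
    stopifnot(all(s == 1 | s == -1))
    id <- as.integer(crossprod(s > 0, 2^(seq_len(N) - 1)))
  } else {
    id <- as.integer(raster)
  }
  if (burn_in > 0) id <- id[-seq_len(burn_in)]
  Tn <- length(id) - 1L
  if (Tn < 1) stop("need at least one transition")
  from <- id[-length(id)]
  to <- id[-1]
  K <- max(id) + 1L
  key <- from * as.double(K) + to
  tab <- table(key)
  cnt <- as.vector(tab)
  kv <- as.numeric(names(tab))
  fi <- floor(kv / K)
  ti <- kv - fi * K
  if (policy == "pseudocount") {
    # one extra count in both directions of every observed (unordered) pair
    pk <- paste(pmin(fi, ti), pmax(fi, ti))
    up <- !duplicated(pk)
    add_f <- c(fi[up], ti[up])
    add_t <- c(ti[up], fi[up])
    allk <- c(kv, add_f * as.double(K) + add_t)
    allc <- c(cnt, rep(1, length(add_f)))
    agg <- tapply(allc, allk, sum)
    kv <- as.numeric(names(agg)); cnt <- as.vector(agg)
    fi <- floor(kv / K); ti <- kv - fi * K
  }
  tot <- sum(cnt)
  f <- cnt / tot                      # empirical flow Pss(i) T(j|i)
  rev_key <- ti * as.double(K) + fi
  ridx <- match(rev_key, kv)
  has_rev <- !is.na(ridx)
  coverage <- sum(f[has_rev])
  keep <- has_rev
  EP <- sum(f[keep] * log(f[keep] / f[ridx[keep]]))
  reliable <- coverage >= min_coverage
  if (!reliable)
    warning("only ", signif(100 * coverage, 3),
            "% of transition flow has an observed reverse; ",
            "entropy-production estimate flagged unreliable")
  list(EP = EP, coverage = coverage, n_states = length(unique(id)),
       n_transitions = Tn, reliable = reliable)
}

#' Pairwise (coupling-based) entropy production
#'
#' The steady-state entropy production of a kinetic Ising network expressed
#' through its couplings and delayed correlations,
#' \eqn{EP = \sum_{ij} (J_{ij} - J_{ji}) B_{ij}}: exactly zero for symmetric
#' couplings regardless of the data. An optional \eqn{\beta} prefactor is
#' available behind \code{with_beta}; the default is the literal
#' coupling-correlation contraction.
#'
#' @param J coupling matrix (\code{N x N}).
#' @param B one-step-delayed correlation matrix
#'   (\eqn{B_{ij} = \langle s_i(t+1) s_j(t)\rangle}), e.g. from
#'   [correlation_stats()].
#' @param beta inverse temperature, used only when \code{with_beta = TRUE}.
#' @param with_beta multiply by \code{beta}.
#' @return Scalar (nats/step).
#' @export
entropy_production_pairwise <- function(J, B, beta = NULL,
                                        with_beta = FALSE) {
  J <- as.matrix(J); B <- as.matrix(B)
  stopifnot(all(dim(J) == dim(B)))
  ep <- sum((J - t(J)) * B)
  if (with_beta) {
    if (is.null(beta)) stop("'beta' required when with_beta = TRUE")
    ep <- beta * ep
  }
  ep
}
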