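test_that("correlation statistics: independence, anti-correlation, frozen flags", {
  set.seed(1)
  coins <- matrix(sign(rnorm(5 * 2e4)), 5, 2e4)
  cs <- correlation_stats(coins, beta = 0.5)
  expect_equal(diag(cs$C), rep(1, 5))
  expect_lt(max(abs(cs$C - diag(5))), 3 / sqrt(2e4) * 1.5)
  expect_lt(max(abs(cs$B)), 3 / sqrt(2e4) * 1.5)

  alt <- matrix(rep(c(1, -1), 50), 1, 100)
  expect_equal(correlation_stats(alt, 1)$B[1, 1], -1)

  frozen <- rbind(rep(1, 100), sign(rnorm(100)))
  expect_warning(csf <- correlation_stats(frozen, 0.5), "frozen")
  expect_identical(csf$frozen, 1L)
  expect_equal(diag(csf$A), 0.5 * c(0, 1 - mean(frozen[2, ])^2))
})

test_that("delayed correlations match the exact stationary chain (N = 3)", {
  net <- random_net(3, beta = 0.6, scale = 0.5, seed = 2)
  B_exact <- exact_delayed_correlation(net)
  s <- simulate(net, nsim = 1e5, seed = 3)
  B_emp <- correlation_stats(s, net$beta)$B
  expect_lt(max(abs(B_emp - B_exact)), 0.02)
})

test_that("gradient inference recovers known couplings and is null-safe", {
  N <- 10; T <- 1e4
  set.seed(4)
  J <- matrix(rnorm(N^2, sd = sqrt(1 / N)), N, N)
  net <- kinetic_ising_net(J, beta = 0.5)
  s <- simulate(net, nsim = T, seed = 5)
  fit <- fit_kinetic_ising(s, beta = 0.5)
  expect_gte(cor(as.vector(coef(fit)), as.vector(J)), 0.9)

  # data with no couplings: estimate stays near zero
  net0 <- kinetic_ising_net(matrix(0, N, N), beta = 0.5)
  s0 <- simulate(net0, nsim = T, seed = 6)
  fit0 <- fit_kinetic_ising(s0, beta = 0.5)
  expect_lte(max(abs(coef(fit0))), 0.1)
})

test_that("objective is non-decreasing and vanishes at the generating model", {
  net <- random_net(6, beta = 0.5, scale = 0.35, seed = 7)
  s <- simulate(net, nsim = 1e4, seed = 8)
  fit <- fit_kinetic_ising(s, beta = 0.5, iters = 400)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  expect_equal(as.numeric(logLik(fit)), kising_loglik(s, fit))

  # moment-matching residuals at the truth are within sampling error
  res <- residuals(fit, s)      # near-zero at the fitted parameters
  expect_lt(max(abs(res)), 4 / sqrt(1e4))
  at_truth <- fit
  at_truth$J <- net$J; at_truth$bias <- net$bias
  expect_lt(max(abs(residuals(at_truth, s))), 3.5 * sqrt(1 / 1e4) * 1.5)
})

test_that("likelihood: uniform kernel value and dominance over shuffled couplings", {
  N <- 10; T <- 1e4
  net0 <- kinetic_ising_net(matrix(0.3, N, N), beta = 0)
  set.seed(9)
  s <- matrix(sign(rnorm(N * T)), N, T)
  expect_equal(kising_loglik(s, net0), -N * (T - 1) * log(2))

  set.seed(10)
  J <- matrix(rnorm(N^2, sd = sqrt(1 / N)), N, N)
  net <- kinetic_ising_net(J, beta = 0.5)
  sim <- simulate(net, nsim = T, seed = 11)
  Jshuf <- matrix(sample(J), N, N)
  expect_gt(kising_loglik(sim, net),
            kising_loglik(sim, kinetic_ising_net(Jshuf, beta = 0.5)))
})

test_that("a constant added to the bias shifts fields exactly as the kernel says", {
  net <- random_net(3, beta = 0.5, seed = 12)
  s0 <- c(1, -1, 1); s1 <- c(-1, 1, 1)
  lp0 <- transition_logprob(net, NULL, s0, s1)
  net$bias <- net$bias + 0.7
  H <- compute_field(net, NULL, s0)
  lp1 <- transition_logprob(net, NULL, s0, s1)
  expect_equal(lp1, sum(0.5 * s1 * H - log(2 * cosh(0.5 * H))))
})

test_that("mean-field inversion: null, weak-coupling recovery, raw variant", {
  set.seed(13)
  coins <- matrix(sign(rnorm(8 * 2e4)), 8, 2e4)
  mf0 <- fit_meanfield(coins, beta = 0.4)
  expect_lt(max(abs(coef(mf0))), 3.5 * sqrt(1 / 2e4) / 0.4 * 1.5)
  mf0_raw <- fit_kinetic_ising(coins, beta = 0.4, method = "meanfield",
                               connected = FALSE)
  expect_lt(max(abs(coef(mf0_raw))), 3.5 * sqrt(1 / 2e4) / 0.4 * 1.5)

  N <- 10
  set.seed(14)
  J <- matrix(rnorm(N^2, sd = sqrt(0.04 / N)), N, N)
  net <- kinetic_ising_net(J, beta = 0.3)
  s <- simulate(net, nsim = 5e4, seed = 15)
  mf <- fit_meanfield(s, beta = 0.3)
  expect_gte(cor(as.vector(coef(mf)), as.vector(J)), 0.8)

  frozen <- rbind(rep(1, 500), sign(rnorm(500)))
  expect_error(suppressWarnings(fit_meanfield(frozen, 0.5)), "singular|frozen")
})

test_that("reconstruction error shrinks with sample size (mean-field)", {
  N <- 8
  set.seed(16)
  J <- matrix(rnorm(N^2, sd = sqrt(0.09 / N)), N, N)
  net <- kinetic_ising_net(J, beta = 0.4)
  err <- sapply(c(1e3, 1e4, 1e5), function(T) {
    median(sapply(1:3, function(k) {
      s <- simulate(net, nsim = T, seed = 100 * k + log10(T))
      sqrt(mean((coef(fit_meanfield(s, 0.4)) - J)^2))
    }))
  })
  expect_true(all(diff(err) < 0))
})

test_that("gradient fit honors a held stimulus drive", {
  set.seed(17)
  d <- 2; N <- 6; T <- 5000
  m <- stimulus_model(d = d, decay = 0.5, noise = 0.1)
  tr <- simulate_linear(m, T = T)
  Phi <- matrix(rnorm(N * d), N, d) * 0.1
  net <- kinetic_ising_net(matrix(rnorm(N * N, sd = 0.2), N, N),
                           beta = 0.5, Phi = Phi)
  s <- simulate(net, stimulus = tr, seed = 18)
  fit <- fit_kinetic_ising(s, beta = 0.5, stimulus = tr, Phi = Phi)
  fit_blind <- fit_kinetic_ising(s, beta = 0.5)
  # knowing the drive gives the better coupling reconstruction
  expect_gt(cor(as.vector(coef(fit)), as.vector(net$J)),
            cor(as.vector(coef(fit_blind)), as.vector(net$J)))
  expect_error(fit_kinetic_ising(s, beta = 0.5, stimulus = tr), "Phi")
})
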