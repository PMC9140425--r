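test_that("degenerate model gives a constant trajectory; seeds reproduce", {
  m <- stimulus_model(d = 2, decay = 0, noise = 0, bounds = NULL)
  tr <- suppressWarnings(simulate_linear(m, T = 50, seed = 1,
                                         x0 = c(2, -3)))
  expect_true(all(tr$x[1, ] == 2))
  expect_true(all(tr$x[2, ] == -3))

  m2 <- stimulus_model(d = 2, decay = 0.5, noise = 0.1, bounds = NULL)
  a <- simulate_linear(m2, T = 500, seed = 42)
  b <- simulate_linear(m2, T = 500, seed = 42)
  expect_identical(a$x, b$x)
  c2 <- simulate_linear(m2, T = 500, seed = 43)
  expect_false(identical(a$x, c2$x))
})

test_that("OU stationary variance and autocorrelation match the closed form", {
  m <- stimulus_model(d = 1, decay = 0.5, noise = 0.1, bounds = NULL)
  T <- 1e5
  tr <- simulate_linear(m, T = T, seed = 7)
  x <- tr$x[1, ]
  # stationary variance sigma^2/(2 alpha) = 0.1 / (2 * 0.5) = 0.1; the
  # standard error accounts for the ~20-step autocorrelation time
  n_eff <- T * m$dt * 2 * 0.5
  expect_lt(abs(var(x) - 0.1), 3 * 0.1 * sqrt(2 / n_eff))
  # lag-tau autocorrelation exp(-alpha tau) at tau = 1, 2, 4 time units
  for (tau in c(1, 2, 4)) {
    k <- round(tau / m$dt)
    emp <- cor(x[seq_len(T - k)], x[seq_len(T - k) + k])
    expect_lt(abs(emp - exp(-0.5 * tau)), 0.05)
  }
})

test_that("stationary moments match the Lyapunov solution for coupled channels", {
  m <- stimulus_model(d = 2, decay = 0.5, cross = 0.4, noise = 0.1,
                      bounds = NULL)
  tr <- simulate_linear(m, T = 1e5, seed = 11)
  P <- lyapunov_cov(m$M, m$Sigma_x)
  emp <- cov(t(tr$x))
  expect_lt(max(abs(emp - P)), 0.15 * max(abs(P)))
  # the directed parameterization hits the requested correlation for d = 2
  expect_lt(abs(cov2cor(P)[1, 2] - 0.4), 1e-8)
  expect_lt(abs(tr$stats$sigma_cross - 0.4), 0.1)
})

test_that("bounding maps into the range and preserves the sign pattern", {
  m <- stimulus_model(d = 2, decay = 0.5, noise = 0.5, bounds = c(-5, 5))
  tr <- simulate_linear(m, T = 5000, seed = 3)
  expect_true(all(tr$x >= -5 & tr$x <= 5))
  raw <- simulate_linear(m, T = 5000, seed = 3, bound = FALSE)
  expect_identical(sign(tr$x), sign(raw$x))
  expect_gt(max(abs(tr$x)), 4.999)  # scaling actually reaches the bound
})

test_that("unstable drift without control raises an error naming the eigenvalue", {
  m <- stimulus_model(d = 1, decay = -0.1, noise = 0.1, bounds = NULL)
  expect_error(simulate_linear(m, T = 100, seed = 1),
               "positive real part")
  # the same drift with a control signal is allowed to run
  m$control <- matrix(0, 1, 100)
  expect_silent(simulate_linear(m, T = 100, seed = 1))
})

test_that("bistable stimulus: p_zero falls with separation; parameter errors", {
  expect_error(simulate_bistable(1, noise_sd = -1, switch_rate = 0.1,
                                 T = 100), "noise_sd")
  expect_error(simulate_bistable(1, noise_sd = 1, switch_rate = 100,
                                 T = 100, dt = 0.1), "switch_rate")
  seps <- c(0, 1.5, 3, 4.5)
  pz <- sapply(seps, function(sep) {
    mean(sapply(1:10, function(s)
      simulate_bistable(sep, noise_sd = 1, switch_rate = 0.05, T = 3000,
                        seed = 1000 * s + round(10 * sep))$stats$p_zero))
  })
  expect_true(all(diff(pz) < 0))   # strictly decreasing in expectation
  # widely separated states leave almost no mass at the midpoint, and the
  # marginal is bimodal: the midpoint bin is emptier than the mode bins
  tr <- simulate_bistable(4, noise_sd = 0.5, switch_rate = 0.05, T = 20000,
                          seed = 5)
  expect_lt(tr$stats$p_zero, 0.02)
  h <- hist(tr$x[1, ], breaks = 30, plot = FALSE)
  mid <- which.min(abs(h$mids))
  expect_lt(h$density[mid], 0.5 * max(h$density))
})

test_that("stimulus statistics: correlations, decay-rate fit, flagged constants", {
  v <- sin(seq_len(500) / 10)
  expect_equal(stimulus_statistics(rbind(v, v))$sigma_cross, 1)

  m <- stimulus_model(d = 2, decay = 0.5, cross = 0, noise = 0.1,
                      bounds = NULL)
  tr <- simulate_linear(m, T = 1e5, seed = 21)
  # independent channels: tolerance from the autocorrelation-inflated SE
  expect_lt(abs(tr$stats$sigma_cross), 4 * sqrt(20 / 1e5))
  # fitted decay rate of the mean autocorrelation
  expect_gt(tr$stats$alpha_scale, 0.4)
  expect_lt(tr$stats$alpha_scale, 0.6)

  const <- rbind(v, rep(1, 500))
  expect_warning(st <- stimulus_statistics(const), "constant")
  expect_true(is.na(st$sigma_cross))
  expect_identical(st$constant_channels, 2L)
})
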