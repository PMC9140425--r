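test_that("linear decoder: orthonormal round trip, constants, linearity", {
  set.seed(1)
  N <- 12; d <- 3
  Phi <- qr.Q(qr(matrix(rnorm(N * d), N, d)))   # orthonormal columns
  cod <- make_codec(N, d, seed = 2)
  cod$Phi <- Phi
  x <- matrix(rnorm(d * 20), d, 20)
  r <- Phi %*% x
  expect_equal(linear_decode(cod, r), x)

  ones <- matrix(1, N, 10)
  xh <- linear_decode(cod, ones)
  expect_equal(xh, matrix(colSums(Phi), d, 10))

  cod2 <- cod; cod2$Phi <- 2 * Phi
  expect_equal(linear_decode(cod2, r), 2 * linear_decode(cod, r))
})

test_that("exponential smoothing keeps dimensions and changes the readout", {
  set.seed(3)
  cod <- make_codec(6, 2, seed = 4)
  ras <- matrix(sign(rnorm(6 * 300)), 6, 300)
  sm <- linear_decode(cod, ras, smooth_tau = 1, dt = 0.1)
  expect_equal(dim(sm), c(2L, 300L))
  expect_false(identical(sm, linear_decode(cod, ras)))
})

test_that("field decoding with exact fields recovers the stimulus", {
  set.seed(5)
  N <- 8; d <- 2; T <- 200
  Phi <- matrix(rnorm(N * d), N, d)
  net <- kinetic_ising_net(matrix(rnorm(N^2, sd = 0.3), N, N), beta = 0.5,
                           Phi = Phi, bias = rnorm(N, sd = 0.1))
  x <- matrix(rnorm(d * T), d, T)
  s <- matrix(sign(rnorm(N * T)), N, T)
  H <- compute_field(net, x, s)
  xh <- field_decode(net, s, H = H)
  expect_lt(max(abs(xh - x)), 1e-4)

  # underdetermined problems are refused
  net_bad <- kinetic_ising_net(matrix(0, 1, 1), Phi = matrix(1:3, 1, 3))
  expect_error(field_decode(net_bad, matrix(1, 1, 5)), "larger network")
  net_rk <- kinetic_ising_net(matrix(0, 4, 4), beta = 0.5,
                              Phi = cbind(1:4, 2 * (1:4)))
  expect_error(field_decode(net_rk, matrix(1, 4, 5)), "rank")
})

test_that("estimated-field decoding beats the instantaneous readout on a driven net", {
  set.seed(6)
  N <- 10; d <- 2; T <- 8000
  m <- stimulus_model(d = d, decay = 0.5, noise = 0.1)
  tr <- simulate_linear(m, T = T)
  cod <- make_codec(N, d, seed = 7)
  net <- kinetic_ising_net(matrix(rnorm(N^2, sd = 0.25), N, N), beta = 0.5,
                           Phi = cod$Phi * 0.1)
  ras <- simulate(net, stimulus = tr, seed = 8)
  D_lin <- decoding_performance(tr, linear_decode(cod, ras))$D
  D_field <- decoding_performance(tr, field_decode(net, ras))$D
  expect_gt(D_field, D_lin)
})

test_that("decoding performance: exact limits, independence, invariances", {
  set.seed(9)
  x <- matrix(rnorm(3 * 500), 3, 500)
  expect_equal(decoding_performance(x, x)$D, 1)
  expect_equal(decoding_performance(x, -x)$D, -1)
  noise <- matrix(rnorm(3 * 500), 3, 500)
  expect_lt(abs(decoding_performance(x, noise)$D), 3 / sqrt(500))

  # positive affine rescaling per channel leaves the score unchanged
  resc <- x * c(2, 0.5, 7) + c(-1, 3, 0)
  expect_equal(decoding_performance(x, resc)$D, 1)

  flat <- x; flat[2, ] <- 5
  expect_warning(p <- decoding_performance(x, flat), "zero-variance")
  expect_true(is.na(p$per_dim[2]))
  expect_equal(p$D, mean(p$per_dim[-2]))

  pf <- decoding_performance(x, resc, aggregate = "flatten")
  expect_true(abs(pf$D) <= 1)
})

test_that("predict dispatches to both decoders from a fit", {
  set.seed(10)
  N <- 6; d <- 2
  m <- stimulus_model(d = d, decay = 0.5)
  tr <- simulate_linear(m, T = 1500)
  cod <- make_codec(N, d, seed = 11)
  code <- sample_spikes(posterior_rate(cod, tr$x), dt = 0.1, seed = 12)
  fit <- fit_kinetic_ising(code$spikes, beta = 0.5, stimulus = tr,
                           Phi = cod$Phi * 0.1, iters = 100)
  xl <- predict(fit, code$spikes, type = "linear")
  xf <- predict(fit, code$spikes, type = "field")
  expect_equal(dim(xl), dim(tr$x))
  expect_equal(dim(xf), dim(tr$x))
  expect_false(identical(xl, xf))
})
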