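test_that("asymmetry ratio: exact values, sentinel, scale invariance", {
  S <- matrix(c(1, 2, 2, -0.5), 2, 2)
  expect_equal(asymmetry(S), 0)
  expect_equal(asymmetry(matrix(c(0, 0, 1, 0), 2, 2)), 1)
  expect_warning(eta <- asymmetry(matrix(c(0, -1, 1, 0), 2, 2)),
                 "rotation")
  expect_identical(eta, Inf)
  set.seed(1)
  J <- matrix(rnorm(25), 5, 5)
  expect_equal(asymmetry(-2.7 * J), asymmetry(J))
})

test_that("pairwise entropy production: hand value and symmetric zero", {
  J <- matrix(c(0, 0, 1, 0), 2, 2, byrow = FALSE)  # J[1,2] = 1
  J <- matrix(0, 2, 2); J[1, 2] <- 1
  B <- matrix(0, 2, 2); B[1, 2] <- 0.5; B[2, 1] <- 0.2
  expect_equal(entropy_production_pairwise(J, B), 0.3)
  expect_equal(entropy_production_pairwise(J, B, beta = 0.5,
                                           with_beta = TRUE), 0.15)
  set.seed(2)
  Js <- matrix(rnorm(16), 4, 4); Js <- Js + t(Js)
  Brand <- matrix(runif(16), 4, 4)
  expect_identical(entropy_production_pairwise(Js, Brand), 0)
})

test_that("a single spin produces no measurable irreversibility", {
  net <- kinetic_ising_net(matrix(0.8, 1, 1), beta = 0.7, bias = 0.2)
  s <- simulate(net, nsim = 2e4, seed = 3)
  ep <- entropy_production_empirical(s)
  expect_lt(ep$EP, 5e-3)
  expect_gte(ep$EP, 0)
})

test_that("biased three-state cycle matches the closed-form rate", {
  # forward p = 0.4, backward q = 0.1, stay 0.5; stationary uniform;
  # EP = (p - q) log(p / q)
  p <- 0.4; q <- 0.1
  ep_true <- (p - q) * log(p / q)
  set.seed(4)
  T <- 3e4
  state <- integer(T); state[1] <- 1
  moves <- runif(T - 1)
  for (t in 1:(T - 1)) {
    state[t + 1] <- if (moves[t] < p) state[t] %% 3 + 1
    else if (moves[t] < p + q) (state[t] - 2) %% 3 + 1
    else state[t]
  }
  # encode the three states as two-spin patterns
  enc <- rbind(c(-1, 1, -1), c(-1, -1, 1))
  ras <- enc[, state]
  ep <- entropy_production_empirical(ras)
  # bootstrap over transitions gives the sampling scale of the estimator
  ep_pairs <- function(from, to) {
    f <- table(factor(from, 1:3), factor(to, 1:3)) / length(from)
    keep <- f > 0 & t(f) > 0
    sum(f[keep] * log(f[keep] / t(f)[keep]))
  }
  from <- state[-T]; to <- state[-1]
  boot <- replicate(60, {
    idx <- sample(T - 1, replace = TRUE)
    ep_pairs(from[idx], to[idx])
  })
  expect_lt(abs(ep$EP - ep_true), 3 * max(sd(boot), 0.005))
  expect_gt(ep$coverage, 0.99)
})

test_that("equilibrium controls produce (near) zero entropy production", {
  net0 <- kinetic_ising_net(matrix(0.4, 4, 4), beta = 0)
  s0 <- simulate(net0, nsim = 1e5, seed = 5)
  expect_lt(entropy_production_empirical(s0)$EP, 0.01)

  set.seed(6)
  J <- matrix(rnorm(16, sd = 0.3), 4, 4); J <- (J + t(J)) / 2
  net <- kinetic_ising_net(J, beta = 0.5)
  s <- simulate(net, nsim = 1e5, seed = 7)
  expect_lt(entropy_production_empirical(s)$EP, 0.01)
})

test_that("pairwise and empirical estimators rank networks consistently", {
  set.seed(8)
  eps <- t(sapply(1:20, function(k) {
    J <- matrix(rnorm(16, sd = 0.5), 4, 4)
    net <- kinetic_ising_net(J, beta = 0.5)
    s <- simulate(net, nsim = 2e4)
    B <- correlation_stats(s, 0.5)$B
    c(pair = entropy_production_pairwise(J, B),
      pair_beta = entropy_production_pairwise(J, B, beta = 0.5,
                                              with_beta = TRUE),
      emp = entropy_production_empirical(s)$EP)
  }))
  expect_gt(cor(eps[, "pair"], eps[, "emp"], method = "spearman"), 0.6)
  expect_gt(cor(eps[, "pair_beta"], eps[, "emp"], method = "spearman"), 0.6)
})

test_that("sparse observations are flagged, pseudocounts give finite output", {
  net <- random_net(8, beta = 0.3, scale = 0.4, seed = 9)
  s <- simulate(net, nsim = 300, seed = 10)   # 2^8 states, 300 steps
  expect_warning(ep <- entropy_production_empirical(s), "unreliable")
  expect_false(ep$reliable)
  ep_pc <- suppressWarnings(
    entropy_production_empirical(s, policy = "pseudocount"))
  expect_true(is.finite(ep_pc$EP))
  expect_error(entropy_production_empirical(matrix(1, 20, 10)), "N <= 14")
})
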