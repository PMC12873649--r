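test_that("dlt_probability evaluates the logistic link", {
  expect_equal(dlt_probability(0, 0), 0.5)
  expect_equal(dlt_probability(qlogis(0.33), 0), 0.33)
  expect_equal(dlt_probability(1.0, 0.5, 2.0), plogis(2.0), tolerance = 1e-12)
  # monotone in both arguments
  expect_true(dlt_probability(1, 0) > dlt_probability(0, 0))
  expect_true(dlt_probability(0, 1) > dlt_probability(0, 0.5))
})

test_that("log-likelihood is cell-additive over treated cells", {
  d <- toy_data()
  expect_equal(log_likelihood(d, c(0, 0, 0), rep(0, 3)), -6 * log(2))
  set.seed(11)
  for (rep in 1:20) {
    beta <- rnorm(3)
    W <- rnorm(3)
    a2 <- runif(1, 0.2, 2)
    expect_equal(log_likelihood(d, beta, W, a2),
                 loglik_oracle(d, beta, W, a2), tolerance = 1e-12)
  }
  # single treated cell, y = 0, beta = W = 0 -> -log 2
  d1 <- trial_data(matrix(0, 1, 1), matrix(1L, 1, 1))
  expect_equal(log_likelihood(d1, 0, 0), -log(2))
  expect_error(log_likelihood(d, c(0, 0), rep(0, 3)))
})

test_that("full conditionals are consistent with likelihood plus prior", {
  d <- toy_data()
  pri <- hier_priors(3, c = c(0.1, 0.3, 0.5))
  beta <- c(-1, 0, 0.5)
  W <- c(0.2, -0.3, 0.1)
  a2 <- 1.4
  # beta_k conditional: differences match full log posterior differences
  for (k in 1:3) {
    f <- log_cond_beta(k, d, W, a2, pri)
    b2 <- beta; b2[k] <- beta[k] + 0.7
    lhs <- f(b2[k]) - f(beta[k])
    rhs <- (log_likelihood(d, b2, W, a2) - log_likelihood(d, beta, W, a2)) +
      dnorm(b2[k], pri$mu[k], sqrt(pri$sigma_beta2), log = TRUE) -
      dnorm(beta[k], pri$mu[k], sqrt(pri$sigma_beta2), log = TRUE)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
  # W_i conditional
  for (i in 1:3) {
    f <- log_cond_W(i, d, beta, 0.8, a2, pri)
    W2 <- W; W2[i] <- W[i] - 0.9
    lhs <- f(W2[i]) - f(W[i])
    rhs <- (log_likelihood(d, beta, W2, a2) - log_likelihood(d, beta, W, a2)) +
      dnorm(W2[i], 0, sqrt(0.8), log = TRUE) -
      dnorm(W[i], 0, sqrt(0.8), log = TRUE)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
  # alpha2 conditional restricted to down-retreat cells
  f <- log_cond_alpha2(d, beta, W, pri)
  lhs <- f(1.8) - f(1.0)
  d_z2 <- d
  keep <- d$treated == 1L & d$assign_type == 2L
  d_z2$treated[!keep] <- 0L
  rhs <- (log_likelihood(d_z2, beta, W, 1.8) -
            log_likelihood(d_z2, beta, W, 1.0)) +
    dnorm(1.8, 1, sqrt(pri$sigma_alpha2), log = TRUE) -
    dnorm(1.0, 1, sqrt(pri$sigma_alpha2), log = TRUE)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("beta conditional reduces to the prior with no data at that dose", {
  d <- toy_data() # dose 3 has one observation; build a dose with none
  pri <- hier_priors(3, c = c(0.1, 0.3, 0.5))
  d$treated[, 3] <- 0L
  f <- log_cond_beta(3, d, rep(0, 3), 1, pri)
  bs <- seq(-3, 3, by = 0.5)
  expect_equal(f(bs) - f(0),
               dnorm(bs, pri$mu[3], sqrt(pri$sigma_beta2), log = TRUE) -
                 dnorm(0, pri$mu[3], sqrt(pri$sigma_beta2), log = TRUE),
               tolerance = 1e-12)
})

test_that("beta conditional mode matches a 1-D optimization oracle", {
  # flat-ish prior, 1 DLT out of 2 at the dose, W = 0 -> mode near logit(0.5)
  y <- matrix(c(1, 0), 2, 1)
  d <- trial_data(y, matrix(1L, 2, 1))
  pri <- hier_priors(1, c = 0.3, sigma_beta2 = 1e6)
  f <- log_cond_beta(1, d, c(0, 0), 1, pri)
  mode <- optimize(f, c(-5, 5), maximum = TRUE)$maximum
  expect_equal(mode, 0, tolerance = 1e-3)
})

test_that("W conditional mode is negative for an all-tolerant patient", {
  y <- matrix(0, 1, 3)
  d <- trial_data(y, matrix(1L, 1, 3))
  pri <- hier_priors(3, c = c(0.2, 0.3, 0.4))
  f <- log_cond_W(1, d, qlogis(c(0.2, 0.3, 0.4)), 1, 1, pri)
  mode <- optimize(f, c(-5, 5), maximum = TRUE)$maximum
  expect_lt(mode, 0)
  # no treated doses -> pure N(0, sigma2) kernel
  d0 <- empty_trial_data(3, 1)
  f0 <- log_cond_W(1, d0, rep(0, 3), 2, 1, pri)
  ws <- seq(-2, 2, 0.5)
  expect_equal(f0(ws) - f0(0), -ws^2 / (2 * 2), tolerance = 1e-12)
})

test_that("conjugate sigma2 update matches the closed form", {
  expect_equal(sample_sigma2(c(0, 0), 1), c(shape = 2, rate = 1))
  expect_equal(sample_sigma2(c(1, 1), 1), c(shape = 2, rate = 2))
  expect_equal(sample_sigma2(c(1, 2, 3), 2), c(shape = 3.5, rate = 9))
  expect_equal(sample_sigma2(numeric(0), 1.5), c(shape = 1.5, rate = 1.5))
})

test_that("Half-Cauchy sigma kernel matches the density-product oracle", {
  W <- c(1, 1)
  tau <- 1
  f <- log_cond_sigma_halfcauchy(W, tau)
  # oracle: log[HalfCauchy(sigma; tau) * prod N(W_i; 0, sigma^2)] up to const
  oracle <- function(s) {
    dcauchy(s, 0, tau, log = TRUE) + sum(dnorm(W, 0, s, log = TRUE))
  }
  s1 <- 0.7; s2 <- 1.9
  expect_equal(f(s1) - f(s2), oracle(s1) - oracle(s2), tolerance = 1e-10)
  # mode matches a grid search
  grid <- seq(0.01, 5, by = 0.001)
  expect_equal(grid[which.max(f(grid))],
               grid[which.max(vapply(grid, oracle, numeric(1)))],
               tolerance = 2e-3)
  expect_identical(f(-1), -Inf)
  # empty W: decreasing tail dominated by -log(tau^2 + sigma^2)
  f0 <- log_cond_sigma_halfcauchy(numeric(0), 1)
  expect_true(all(diff(f0(seq(2, 50, by = 1))) < 0))
})

test_that("alpha2 conditional reduces to its prior without down-retreats", {
  d <- quad_fixture_data(c(0, 1)) # no Z = 2 cells
  pri <- hier_priors(2, c = c(0.2, 0.4), sigma_alpha2 = 0.5)
  f <- log_cond_alpha2(d, c(0, 0), c(0, 0), pri)
  as <- seq(-1, 3, 0.25)
  expect_equal(f(as) - f(1), -(as - 1)^2 / (2 * 0.5), tolerance = 1e-12)
})

test_that("posterior sampling is seed-deterministic", {
  d <- toy_data()
  pri <- hier_priors(3, c = c(0.1, 0.3, 0.5))
  a <- sample_posterior(d, pri, "pride_fa", n_samples = 200, seed = 7)
  b <- sample_posterior(d, pri, "pride_fa", n_samples = 200, seed = 7)
  expect_identical(a$beta, b$beta)
  expect_identical(a$W, b$W)
  expect_identical(a$sigma2, b$sigma2)
  expect_identical(a$alpha2, b$alpha2)
  expect_true(all(a$sigma2 > 0))
})

test_that("alpha2 is fixed at 1 under up-only retreatment", {
  d <- toy_data()
  pri <- hier_priors(3, c = c(0.1, 0.3, 0.5))
  dr <- sample_posterior(d, pri, "pride", n_samples = 100, seed = 3)
  expect_true(all(dr$alpha2 == 1))
})

test_that("posterior dose rates reflect the draws", {
  d <- toy_data()
  pri <- hier_priors(3, c = c(0.1, 0.3, 0.5))
  dr <- sample_posterior(d, pri, "pride", n_samples = 50, seed = 5)
  r <- posterior_dose_rates(dr)
  expect_equal(r, plogis(dr$beta))
  expect_true(all(r > 0 & r < 1))
  rm <- posterior_dose_rates(dr, marginalize = TRUE)
  expect_equal(dim(rm), dim(r))
})

test_that("sampler matches quadrature oracle for Pr(p1 > phi)", {
  pri <- hier_priors(2, c = c(0.2, 0.4), sigma_beta2 = 2)
  for (yy in list(c(1, 0), c(0, 0), c(1, 1))) {
    d <- quad_fixture_data(yy)
    oracle <- quadrature_pr_oracle(yy, pri, sigma2 = 1, phi = 0.33)
    dr <- sample_posterior(d, pri, "pride", n_samples = 60000, seed = 21,
                           fix_sigma2 = 1)
    mc <- mean(plogis(dr$beta[, 1]) > 0.33)
    expect_lt(abs(mc - oracle), 0.03)
  }
})

test_that("posterior means recover truth from model-simulated patients", {
  set.seed(99)
  K <- 5
  truth <- c(0.10, 0.20, 0.33, 0.45, 0.60)
  beta_true <- qlogis(truth)
  sigma2_true <- 0.5
  n <- 200
  y <- matrix(NA_real_, n, K)
  tr <- matrix(0L, n, K)
  for (i in seq_len(n)) {
    w <- rnorm(1, 0, sqrt(sigma2_true))
    start <- sample.int(K, 1)
    doses <- start:min(start + sample.int(3, 1) - 1, K)
    for (k in doses) {
      tr[i, k] <- 1L
      y[i, k] <- rbinom(1, 1, plogis(beta_true[k] + w))
    }
  }
  d <- trial_data(y, tr)
  pri <- hier_priors(K)
  dr <- sample_posterior(d, pri, "pride", n_samples = 2000, seed = 123)
  est <- colMeans(plogis(dr$beta))
  expect_lt(mean(abs(est - truth)), 0.05)
})

test_that("posterior draws export to CSV", {
  d <- toy_data()
  pri <- hier_priors(3, c = c(0.1, 0.3, 0.5))
  dr <- sample_posterior(d, pri, "pride", n_samples = 20, seed = 2)
  f <- tempfile(fileext = ".csv")
  write_posterior_draws(dr, f)
  out <- read.csv(f)
  expect_equal(nrow(out), 20)
  expect_equal(out$beta1, dr$beta[, 1])
  unlink(f)
})
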