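# Shared fixtures and independent oracles for the test suite.

# Small trial data: 3 patients, 3 doses, mixed histories.
toy_data <- function() {
  y <- matrix(NA_real_, 3, 3)
  tr <- matrix(0L, 3, 3)
  zt <- matrix(1L, 3, 3)
  # patient 1: doses 1 (no DLT), 2 (DLT)
  tr[1, 1:2] <- 1L; y[1, 1] <- 0; y[1, 2] <- 1
  # patient 2: dose 1 (no DLT)
  tr[2, 1] <- 1L; y[2, 1] <- 0
  # patient 3: doses 2 (no DLT), 3 (no DLT), 1 (down-retreat, no DLT)
  tr[3, c(1, 2, 3)] <- 1L; y[3, ] <- 0; zt[3, 1] <- 2L
  trial_data(y, tr, zt)
}

# Independent per-cell log-likelihood oracle: explicit double loop over
# dbinom log masses, no shared code with the implementation.
loglik_oracle <- function(data, beta, W, alpha2 = 1) {
  total <- 0
  for (i in seq_len(data$n_patients)) {
    for (k in seq_len(data$n_doses)) {
      if (data$treated[i, k] == 1L) {
        a <- if (data$assign_type[i, k] == 2L) alpha2 else 1
        p <- 1 / (1 + exp(-(beta[k] + a * W[i])))
        total <- total + dbinom(data$y[i, k], 1, p, log = TRUE)
      }
    }
  }
  total
}

# Inverse-gamma CDF via the gamma identity P(1/G <= x) = P(G >= rate/x).
pinvgamma <- function(q, shape, rate) {
  ifelse(q <= 0, 0, 1 - pgamma(rate / q, shape = shape))
}

# 3-D quadrature oracle for Pr(p_1 > phi | data) on a fixture where only
# dose 1 carries observations: grid over (beta1, W1, W2), sigma2 fixed.
# The beta grid must be fine because the tail indicator 1{beta > logit(phi)}
# is discontinuous; the W integrand is smooth, so a coarser grid suffices.
quadrature_pr_oracle <- function(y_obs, priors, sigma2, phi,
                                 ngrid = 201, nb = 8001) {
  mu1 <- priors$mu[1]
  sb <- sqrt(priors$sigma_beta2)
  s <- sqrt(sigma2)
  b <- seq(mu1 - 6 * sb, mu1 + 6 * sb, length.out = nb)
  w <- seq(-6 * s, 6 * s, length.out = ngrid)
  lik_cell <- function(bb, ww, yy) {
    p <- plogis(bb + ww)
    if (yy == 1) p else 1 - p
  }
  # weights: prior(beta1) x prior(W1) x prior(W2) x lik(y1|b,W1) x lik(y2|b,W2)
  pb <- dnorm(b, mu1, sb)
  pw <- dnorm(w, 0, s)
  l1 <- outer(b, w, function(bb, ww) lik_cell(bb, ww, y_obs[1]))
  l2 <- outer(b, w, function(bb, ww) lik_cell(bb, ww, y_obs[2]))
  m1 <- (l1 * rep(pw, each = length(b))) %*% rep(1, length(w)) # sum over W1
  m2 <- (l2 * rep(pw, each = length(b))) %*% rep(1, length(w)) # sum over W2
  post_b <- pb * as.numeric(m1) * as.numeric(m2)
  sum(post_b[b > qlogis(phi)]) / sum(post_b)
}

# two patients, two doses, observations at dose 1 only
quad_fixture_data <- function(y_obs) {
  y <- matrix(NA_real_, 2, 2)
  tr <- matrix(0L, 2, 2)
  tr[, 1] <- 1L
  y[1, 1] <- y_obs[1]
  y[2, 1] <- y_obs[2]
  trial_data(y, tr)
}

default_config <- function(...) {
  design_config(phi = 0.33, n_doses = 5, ...)
}
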