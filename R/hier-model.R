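#' Per-cell DLT probability
#'
#' The hierarchical logistic toxicity model puts
#' `logit(p_ik) = beta_k + alpha * W_i`, where `beta_k` is the dose effect,
#' `W_i` the patient random effect and `alpha` a scaling factor that equals 1
#' for newly enrolled and up-retreated patients and is estimated for
#' down-retreated patients under flexible allocation.
#'
#' @param beta_k dose effect (logit scale).
#' @param W_i patient random effect.
#' @param alpha random-effect scaling (default 1).
#' @return probability in (0, 1), increasing in `beta_k` and `alpha * W_i`.
#' @examples
#' dlt_probability(0, 0)            # 0.5
#' dlt_probability(qlogis(0.33), 0) # 0.33
#' @export
dlt_probability <- function(beta_k, W_i, alpha = 1) {
  stats::plogis(beta_k + alpha * W_i)
}

# Stable log(1 + exp(x))
log1pexp <- function(x) {
  out <- numeric(length(x))
  lo <- x <= -37
  mid <- !lo & x <= 18
  hi2 <- !lo & !mid & x <= 33.3
  top <- x > 33.3
  out[lo] <- exp(x[lo])
  out[mid] <- log1p(exp(x[mid]))
  out[hi2] <- x[hi2] + exp(-x[hi2])
  out[top] <- x[top]
  out
}

# Linear predictor matrix beta_k + alpha_{Z_ik} W_i for treated cells.
linear_predictor <- function(data, beta, W, alpha2) {
  a <- ifelse(data$assign_type == 2L, alpha2, 1)
  outer(W, beta, function(w, b) b) + a * matrix(W, data$n_patients,
                                                data$n_doses)
}

#' Conditional log-likelihood of the observed data
#'
#' Sum over treated cells of the Bernoulli-logit log mass
#' `y_ik * lp_ik - log(1 + exp(lp_ik))` with
#' `lp_ik = beta_k + alpha_{Z_ik} W_i`; untreated cells contribute zero.
#'
#' @param data a [trial_data] object.
#' @param beta dose-effect vector (length K).
#' @param W patient random-effect vector (length n).
#' @param alpha2 down-retreat scaling (1 under up-only retreatment).
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(data, beta, W, alpha2 = 1) {
  stopifnot(inherits(data, "trial_data"),
            length(beta) == data$n_doses, length(W) == data$n_patients)
  if (data$n_patients == 0 || sum(data$treated) == 0) return(0)
  lp <- linear_predictor(data, beta, W, alpha2)
  cells <- data$treated == 1L
  sum(data$y[cells] * lp[cells] - log1pexp(lp[cells]))
}

#' Full conditional log-densities (proportional form)
#'
#' Each function returns a vectorized log-density function of one real
#' argument, proportional to the full conditional under the hierarchical
#' model. These are the kernels the Metropolis-within-Gibbs sampler targets;
#' they are exposed for testing and diagnostics.
#'
#' @param k dose index.
#' @param data a [trial_data] object.
#' @param W patient random effects.
#' @param alpha2 down-retreat scaling.
#' @param priors a [hier_priors] object.
#' @return function of one real returning the log kernel.
#' @export
log_cond_beta <- function(k, data, W, alpha2, priors) {
  stopifnot(k >= 1, k <= data$n_doses)
  idx <- which(data$treated[, k] == 1L)
  yv <- data$y[idx, k]
  av <- ifelse(data$assign_type[idx, k] == 2L, alpha2, 1)
  aw <- av * W[idx]
  mu_k <- priors$mu[k]
  sb2 <- priors$sigma_beta2
  function(b) {
    vapply(b, function(bb) {
      lp <- bb + aw
      sum(yv * lp - log1pexp(lp)) - (bb - mu_k)^2 / (2 * sb2)
    }, numeric(1))
  }
}

#' @rdname log_cond_beta
#' @param i patient index.
#' @param beta dose effects.
#' @param sigma2 random-effect variance.
#' @export
log_cond_W <- function(i, data, beta, sigma2, alpha2, priors) {
  stopifnot(sigma2 > 0, i >= 1, i <= data$n_patients)
  idx <- which(data$treated[i, ] == 1L)
  yv <- data$y[i, idx]
  av <- ifelse(data$assign_type[i, idx] == 2L, alpha2, 1)
  bv <- beta[idx]
  function(w) {
    vapply(w, function(ww) {
      lp <- bv + av * ww
      sum(yv * lp - log1pexp(lp)) - ww^2 / (2 * sigma2)
    }, numeric(1))
  }
}

#' @rdname log_cond_beta
#' @export
log_cond_alpha2 <- function(data, beta, W, priors) {
  cells <- which(data$treated == 1L & data$assign_type == 2L, arr.ind = TRUE)
  yv <- data$y[cells]
  bv <- beta[cells[, 2]]
  wv <- W[cells[, 1]]
  sa2 <- priors$sigma_alpha2
  function(a) {
    vapply(a, function(aa) {
      if (length(yv)) {
        lp <- bv + aa * wv
        sum(yv * lp - log1pexp(lp)) - (aa - 1)^2 / (2 * sa2)
      } else {
        -(aa - 1)^2 / (2 * sa2)
      }
    }, numeric(1))
  }
}

#' Conjugate update of the random-effect variance
#'
#' With prior sigma2 ~ Inv-Gamma(eta, eta) and W_i | sigma2 ~ N(0, sigma2),
#' the conditional posterior is Inv-Gamma(eta + n/2, eta + sum(W_i^2)/2).
#'
#' @param W random-effect vector (may be empty: the posterior is the prior).
#' @param eta Inv-Gamma hyperparameter (> 0).
#' @return named vector `c(shape, rate)` of the Inv-Gamma posterior.
#' @examples
#' sample_sigma2(c(1, 1), eta = 1) # shape 2, rate 2
#' @export
sample_sigma2 <- function(W, eta) {
  stopifnot(eta > 0)
  c(shape = eta + length(W) / 2, rate = eta + sum(W^2) / 2)
}

#' Draw from an inverse-gamma distribution
#' @param n number of draws.
#' @param shape,rate Inv-Gamma parameters.
#' @export
rinvgamma <- function(n, shape, rate) {
  rate / stats::rgamma(n, shape = shape)
}

#' Log conditional kernel of sigma under a Half-Cauchy prior
#'
#' With sigma ~ Half-Cauchy(0, tau) and W_i | sigma ~ N(0, sigma^2), the log
#' conditional kernel of sigma (up to a constant) is
#' `-(n log sigma + sum(W^2)/(2 sigma^2) + log(tau^2 + sigma^2))`;
#' higher values mean higher density.
#'
#' @param W random-effect vector.
#' @param tau Half-Cauchy scale (> 0).
#' @return vectorized log-kernel function of sigma; -Inf for sigma <= 0.
#' @export
log_cond_sigma_halfcauchy <- function(W, tau) {
  stopifnot(tau > 0)
  n <- length(W)
  ss <- sum(W^2)
  function(sigma) {
    ifelse(sigma > 0,
           -(n * log(sigma) + ss / (2 * sigma^2) + log(tau^2 + sigma^2)),
           -Inf)
  }
}

#' Posterior sampling for the hierarchical toxicity model
#'
#' Metropolis-Hastings-within-Gibbs sampler. Dose effects `beta_k` and
#' patient effects `W_i` are updated by Gaussian random-walk MH with step
#' sizes adapted during burn-in toward a 30-45% acceptance rate; `sigma2`
#' is drawn exactly from its conjugate Inv-Gamma conditional (or by MH on
#' `log sigma` under the Half-Cauchy prior); `alpha2` is updated by MH under
#' flexible allocation and held at 1 otherwise. Initialization:
#' `beta = mu`, `W = 0`, `sigma2 = 1`, `alpha2 = 1` (prior-centered).
#'
#' @param data a [trial_data] object.
#' @param priors a [hier_priors] object.
#' @param scheme `"pride"` (up-only retreatment, alpha2 fixed at 1) or
#'   `"pride_fa"` (flexible allocation, alpha2 sampled).
#' @param n_samples retained draws (default 2000).
#' @param burnin burn-in iterations (default `n_samples`).
#' @param seed optional integer seed (draws are reproducible given it).
#' @param random_effects set `FALSE` to freeze `W = 0` (correlation-free
#'   variant used by the AIDE/IPDE baselines).
#' @param fix_sigma2 optional fixed value for sigma2 (skips its update).
#' @return object of class `posterior_draws`: list with matrix `beta`
#'   (S x K), matrix `W` (S x n), vectors `sigma2` and `alpha2`.
#' @export
sample_posterior <- function(data, priors, scheme = c("pride", "pride_fa"),
                             n_samples = 2000, burnin = n_samples,
                             seed = NULL, random_effects = TRUE,
                             fix_sigma2 = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(data, "trial_data"), inherits(priors, "hier_priors"),
            data$n_doses == priors$n_doses, n_samples >= 1)
  if (!is.null(seed)) set.seed(seed)
  y <- data$y
  y[data$treated == 0L] <- 0
  storage.mode(y) <- "integer"
  fit <- .gibbs_sampler(
    y, data$treated, data$assign_type, priors$mu, priors$sigma_beta2,
    if (priors$variance_prior == "inv_gamma") 0L else 1L,
    priors$eta, priors$tau,
    scheme == "pride_fa", priors$sigma_alpha2,
    random_effects,
    if (is.null(fix_sigma2)) -1 else fix_sigma2,
    as.integer(n_samples), as.integer(burnin)
  )
  if (any(!is.finite(fit$beta))) stop("non-finite posterior draws")
  structure(
    list(beta = fit$beta, W = fit$W, sigma2 = as.numeric(fit$sigma2),
         alpha2 = as.numeric(fit$alpha2), n_samples = n_samples,
         scheme = scheme),
    class = "posterior_draws"
  )
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("posterior_draws:", x$n_samples, "retained draws,",
      ncol(x$beta), "doses,", ncol(x$W), "patients, scheme:", x$scheme, "\n")
  cat("  posterior mean dose rates:",
      paste(round(colMeans(stats::plogis(x$beta)), 3), collapse = " "), "\n")
  invisible(x)
}

#' Per-draw population DLT rates
#'
#' Dose-level DLT rates evaluated at the reference patient `W = 0`:
#' `p_k = plogis(beta_k)` for each draw. Optionally the patient effect is
#' integrated out by Monte Carlo, drawing one `W ~ N(0, sigma2)` per posterior
#' draw.
#'
#' @param draws a `posterior_draws` object.
#' @param marginalize integrate over the random-effect distribution instead
#'   of using the reference patient (default `FALSE`).
#' @return S x K matrix of probabilities.
#' @export
posterior_dose_rates <- function(draws, marginalize = FALSE) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (!marginalize) {
    stats::plogis(draws$beta)
  } else {
    w <- stats::rnorm(nrow(draws$beta), 0, sqrt(draws$sigma2))
    stats::plogis(draws$beta + w)
  }
}

#' Export posterior draws to CSV
#' @param draws a `posterior_draws` object.
#' @param file output path.
#' @export
write_posterior_draws <- function(draws, file) {
  df <- as.data.frame(cbind(draws$beta, draws$sigma2, draws$alpha2))
  names(df) <- c(paste0("beta", seq_len(ncol(draws$beta))), "sigma2", "alpha2")
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
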