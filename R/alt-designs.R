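#' Optimal BOIN interval boundaries
#'
#' Closed-form escalation/de-escalation boundaries of the Bayesian optimal
#' interval design, using the default alternatives `phi1 = 0.6 phi`
#' (under-dosing) and `phi2 = 1.4 phi` (over-dosing):
#' \deqn{\lambda_e = \frac{\log((1-\phi_1)/(1-\phi))}
#'   {\log(\phi(1-\phi_1)/(\phi_1(1-\phi)))}, \quad
#' \lambda_d = \frac{\log((1-\phi)/(1-\phi_2))}
#'   {\log(\phi_2(1-\phi)/(\phi(1-\phi_2)))}.}
#'
#' @param phi target DLT rate in (0, 1).
#' @param phi1,phi2 under/over-dosing alternatives (defaults 0.6/1.4 phi).
#' @return object of class `boin_boundaries`: list with `lambda_e`,
#'   `lambda_d` satisfying `lambda_e < phi < lambda_d`.
#' @examples
#' boin_boundaries(0.2) # lambda_e ~ 0.157, lambda_d ~ 0.238
#' @export
boin_boundaries <- function(phi, phi1 = 0.6 * phi, phi2 = 1.4 * phi) {
  stopifnot(phi > 0, phi < 1, phi1 < phi, phi2 > phi, phi2 < 1)
  lambda_e <- log((1 - phi1) / (1 - phi)) /
    log(phi * (1 - phi1) / (phi1 * (1 - phi)))
  lambda_d <- log((1 - phi) / (1 - phi2)) /
    log(phi2 * (1 - phi) / (phi * (1 - phi2)))
  structure(list(lambda_e = lambda_e, lambda_d = lambda_d, phi = phi),
            class = "boin_boundaries")
}

#' BOIN dose-movement decision
#'
#' Escalate when the estimated DLT rate at the current dose is at or below
#' `lambda_e`, de-escalate when strictly above `lambda_d`, stay otherwise.
#' The estimate is the observed fraction `y_k / n_k` in the standard design,
#' or the hierarchical posterior mean of `p_k` when the retreatment scheme's
#' model is plugged in.
#'
#' @param rate_estimate estimated DLT rate at the current dose, in [0, 1].
#' @param boundaries a `boin_boundaries` object.
#' @return one of `"de_escalate"`, `"stay"`, `"escalate"`.
#' @export
boin_decide <- function(rate_estimate, boundaries) {
  stopifnot(inherits(boundaries, "boin_boundaries"),
            rate_estimate >= 0, rate_estimate <= 1)
  if (rate_estimate <= boundaries$lambda_e) "escalate"
  else if (rate_estimate > boundaries$lambda_d) "de_escalate"
  else "stay"
}

#' CRM with patient random effects
#'
#' Two-parameter logistic continual reassessment model extended with patient
#' random effects: `logit p_ik = beta0 + beta1 * d_k + W_i` with `beta1 > 0`
#' (sampled on the log scale) and `W_i ~ N(0, sigma2)`. Effective doses are
#' back-solved from the skeleton at the prior means (`d_k = logit(skeleton_k)`).
#' Priors: `beta0 ~ N(0, 4)`, `log beta1 ~ N(0, 1)`, `sigma2 ~
#' Inv-Gamma(eta, eta)`. The recommended next dose is the one whose posterior
#' mean population rate `plogis(beta0 + beta1 d_k)` is closest to the target.
#'
#' @param data a [trial_data] object.
#' @param skeleton strictly increasing prior toxicity probabilities.
#' @param phi target DLT rate.
#' @param eta Inv-Gamma hyperparameter for sigma2 (default 1).
#' @param n_samples retained posterior draws (default 2000).
#' @param burnin burn-in iterations (default `n_samples`).
#' @param seed optional integer seed.
#' @param random_effects set `FALSE` for the ordinary two-parameter CRM
#'   (`W` frozen at 0).
#' @return list with draws `beta0`, `beta1`, `W`, `sigma2`, matrix `rates`
#'   (S x K posterior population rates), and `next_dose`.
#' @export
crm_random_effects <- function(data, skeleton, phi, eta = 1,
                               n_samples = 2000, burnin = n_samples,
                               seed = NULL, random_effects = TRUE) {
  stopifnot(inherits(data, "trial_data"),
            length(skeleton) == data$n_doses,
            all(diff(skeleton) > 0), all(skeleton > 0 & skeleton < 1))
  if (!is.null(seed)) set.seed(seed)
  y <- data$y
  y[data$treated == 0L] <- 0
  storage.mode(y) <- "integer"
  d <- stats::qlogis(skeleton)
  fit <- .crm_sampler(y, data$treated, d, 4, 1, eta, random_effects,
                      as.integer(n_samples), as.integer(burnin))
  rates <- stats::plogis(outer(fit$beta0, rep(1, length(d))) +
                           outer(fit$beta1, d))
  post_mean <- colMeans(rates)
  list(beta0 = as.numeric(fit$beta0), beta1 = as.numeric(fit$beta1),
       W = fit$W, sigma2 = as.numeric(fit$sigma2), rates = rates,
       post_mean = post_mean,
       next_dose = which.min(abs(post_mean - phi)))
}
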