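#' Prior specification for the hierarchical toxicity model
#'
#' Dose effects get independent normal priors beta_k ~ N(mu_k, sigma_beta2)
#' with mu_k = logit(c_k) for a pre-specified increasing skeleton c of
#' expected toxicity probabilities; the monotone skeleton encodes the
#' monotone dose-toxicity assumption. Patient random effects are
#' W_i | sigma2 ~ N(0, sigma2). The random-effect variance takes either the
#' conjugate sigma2 ~ Inv-Gamma(eta, eta) prior or, alternatively,
#' sigma ~ Half-Cauchy(0, tau). Under flexible allocation the down-retreat
#' scaling parameter alpha2 has prior N(1, sigma_alpha2).
#'
#' @param n_doses number of dose levels K.
#' @param c skeleton of prior toxicity probabilities, strictly increasing in
#'   (0,1); default equally spaced from 0.1 to 0.5 over K doses.
#' @param sigma_beta2 prior variance of the dose effects (default 10).
#' @param variance_prior `"inv_gamma"` (default) or `"half_cauchy"`.
#' @param eta Inv-Gamma(eta, eta) hyperparameter (default 1).
#' @param tau Half-Cauchy scale for sigma (default 1).
#' @param sigma_alpha2 prior variance of alpha2 (default 1).
#' @return object of class `hier_priors`.
#' @examples
#' hier_priors(5)
#' @export
hier_priors <- function(n_doses,
                        c = seq(0.1, 0.5, length.out = n_doses),
                        sigma_beta2 = 10,
                        variance_prior = c("inv_gamma", "half_cauchy"),
                        eta = 1, tau = 1, sigma_alpha2 = 1) {
  variance_prior <- match.arg(variance_prior)
  stopifnot(length(c) == n_doses, all(c > 0 & c < 1), all(diff(c) > 0),
            sigma_beta2 > 0, eta > 0, tau > 0, sigma_alpha2 > 0)
  structure(
    list(n_doses = as.integer(n_doses), c = c, mu = stats::qlogis(c),
         sigma_beta2 = sigma_beta2, variance_prior = variance_prior,
         eta = eta, tau = tau, sigma_alpha2 = sigma_alpha2),
    class = "hier_priors"
  )
}

#' @export
print.hier_priors <- function(x, ...) {
  cat("hier_priors: K =", x$n_doses,
      "skeleton =", paste(round(x$c, 3), collapse = ", "), "\n")
  cat("  beta_k ~ N(logit c_k,", x$sigma_beta2, ")\n")
  if (x$variance_prior == "inv_gamma") {
    cat("  sigma2 ~ Inv-Gamma(", x$eta, ",", x$eta, ")\n")
  } else {
    cat("  sigma ~ Half-Cauchy(0,", x$tau, ")\n")
  }
  cat("  alpha2 ~ N(1,", x$sigma_alpha2, ") (flexible allocation only)\n")
  invisible(x)
}
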