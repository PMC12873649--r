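#' Posterior odds of over-toxicity at the current dose and its neighbors
#'
#' For each of the left, current and right doses, computes the odds
#' `O_k = Pr(p_k > phi) / Pr(p_k <= phi)` from posterior rate samples.
#' Empirical fractions of 0 or 1 are clipped to `[1/(S+1), S/(S+1)]` before
#' forming the ratio (pseudo-count regularization, avoids division by zero).
#'
#' @param rate_samples S x K matrix of posterior DLT-rate samples (e.g., from
#'   [posterior_dose_rates()]).
#' @param current current dose index.
#' @param phi target DLT rate.
#' @return object of class `odds_triple`: list with `O_L`, `O_C`, `O_R`
#'   (NA where the neighbor does not exist) and `has_left`, `has_right`.
#' @export
compute_odds <- function(rate_samples, current, phi) {
  rate_samples <- as.matrix(rate_samples)
  K <- ncol(rate_samples)
  S <- nrow(rate_samples)
  stopifnot(current >= 1, current <= K, S >= 1)
  odds1 <- function(k) {
    f <- mean(rate_samples[, k] > phi)
    f <- min(max(f, 1 / (S + 1)), S / (S + 1))
    f / (1 - f)
  }
  structure(
    list(O_L = if (current > 1) odds1(current - 1) else NA_real_,
         O_C = odds1(current),
         O_R = if (current < K) odds1(current + 1) else NA_real_,
         has_left = current > 1, has_right = current < K),
    class = "odds_triple"
  )
}

#' Analytic over-toxicity odds from per-dose counts
#'
#' Beta-binomial route used by the standard (single-dose-per-patient) CFO
#' baseline and by the threshold calibration: with prior
#' `p ~ Beta(phi, 1 - phi)` and `y` DLTs out of `n`, the posterior is
#' `Beta(phi + y, 1 - phi + n - y)` and `O = Pr(p > phi) / Pr(p <= phi)`.
#'
#' @param y DLT count(s).
#' @param n treated count(s).
#' @param phi target DLT rate.
#' @return odds (vectorized over `y`, `n`).
#' @export
beta_binomial_odds <- function(y, n, phi) {
  pr <- 1 - stats::pbeta(phi, phi + y, 1 - phi + n - y)
  pr / (1 - pr)
}

#' @rdname compute_odds
#' @param y_k,n_k per-dose DLT and treatment counts.
#' @export
compute_odds_counts <- function(y_k, n_k, current, phi) {
  K <- length(n_k)
  stopifnot(current >= 1, current <= K, length(y_k) == K)
  odds1 <- function(k) beta_binomial_odds(y_k[k], n_k[k], phi)
  structure(
    list(O_L = if (current > 1) odds1(current - 1) else NA_real_,
         O_C = odds1(current),
         O_R = if (current < K) odds1(current + 1) else NA_real_,
         has_left = current > 1, has_right = current < K),
    class = "odds_triple"
  )
}

#' Calibration-free odds dose-movement decision
#'
#' The current dose competes against its neighbors through two odds ratios:
#' the de-escalation statistic `O_C / Obar_L = O_C * O_L` (large when the
#' current dose looks toxic and the left dose tolerable) and the escalation
#' statistic `Obar_C / O_R = 1 / (O_C * O_R)` (large when the current dose
#' looks tolerable and the right dose not clearly toxic). Decisions follow
#' the two-condition rule: both exceed their thresholds or neither does ->
#' stay; only the de-escalation condition holds -> de-escalate; only the
#' escalation condition holds -> escalate. A missing neighbor makes its
#' condition fail.
#'
#' @param odds an `odds_triple` from [compute_odds()].
#' @param gammas a `gamma_thresholds` from [calibrate_gammas()].
#' @return one of `"de_escalate"`, `"stay"`, `"escalate"`.
#' @export
cfo_decide <- function(odds, gammas) {
  stopifnot(inherits(odds, "odds_triple"))
  de <- odds$has_left && (odds$O_C * odds$O_L > gammas$gamma_L)
  esc <- odds$has_right && (1 / (odds$O_C * odds$O_R) > gammas$gamma_R)
  if (de && esc) "stay"
  else if (de) "de_escalate"
  else if (esc) "escalate"
  else "stay"
}

# Error probability of a thresholded odds-ratio decision by exact
# enumeration of the joint binomial outcome distribution.
# stat_fn(y_a, y_b) is the decision statistic; decide "move" iff stat > gamma.
# H0: moving is wrong (p under null); H1: moving is right.
enumerate_gamma <- function(n_a, n_b, p_a0, p_b0, p_a1, p_b1, stat) {
  ya <- 0:n_a
  yb <- 0:n_b
  g <- expand.grid(ya = ya, yb = yb)
  tval <- stat(g$ya, g$yb)
  w0 <- stats::dbinom(g$ya, n_a, p_a0) * stats::dbinom(g$yb, n_b, p_b0)
  w1 <- stats::dbinom(g$ya, n_a, p_a1) * stats::dbinom(g$yb, n_b, p_b1)
  ts <- sort(unique(tval))
  # candidate thresholds between consecutive achievable statistic values
  cand <- if (length(ts) > 1) {
    exp((log(ts[-1]) + log(ts[-length(ts)])) / 2)
  } else {
    ts
  }
  cand <- c(cand, ts[length(ts)] * 2)
  err <- vapply(cand, function(gm) {
    sum(w0[tval > gm]) + sum(w1[tval <= gm])
  }, numeric(1))
  list(gamma = cand[which.min(err)], error = min(err))
}

#' Calibrate the CFO odds-ratio thresholds
#'
#' Thresholds `gamma_L` and `gamma_R` are chosen to minimize the probability
#' of an incorrect move under two simple hypotheses separated by `delta`
#' around the target, with beta-binomial evidence (prior `Beta(phi, 1-phi)`).
#' For the de-escalation comparison, the null is (p_L, p_C) = (phi - delta,
#' phi) (staying is correct) and the alternative (phi, phi + delta)
#' (de-escalating is correct); symmetrically for escalation. The
#' minimization enumerates all outcome pairs exactly. When either side has
#' no observations the threshold defaults to 1.
#'
#' @param n_L,n_C,n_R current sample sizes at the left, current and right
#'   doses (use 0 for a missing neighbor).
#' @param phi target DLT rate.
#' @param delta hypothesis separation (default 0.1).
#' @return object of class `gamma_thresholds`: list with `gamma_L`,
#'   `gamma_R` (both > 0).
#' @export
calibrate_gammas <- function(n_L, n_C, n_R, phi, delta = 0.1) {
  stopifnot(n_L >= 0, n_C >= 0, n_R >= 0, phi > 0, phi < 1)
  p_lo <- max(phi - delta, 1e-3)
  p_hi <- min(phi + delta, 1 - 1e-3)
  gamma_L <- if (n_L >= 1 && n_C >= 1) {
    enumerate_gamma(
      n_L, n_C, p_a0 = p_lo, p_b0 = phi, p_a1 = phi, p_b1 = p_hi,
      stat = function(yl, yc) {
        beta_binomial_odds(yc, n_C, phi) * beta_binomial_odds(yl, n_L, phi)
      }
    )$gamma
  } else 1
  gamma_R <- if (n_C >= 1 && n_R >= 1) {
    enumerate_gamma(
      n_C, n_R, p_a0 = phi, p_b0 = p_hi, p_a1 = p_lo, p_b1 = phi,
      stat = function(yc, yr) {
        1 / (beta_binomial_odds(yc, n_C, phi) *
               beta_binomial_odds(yr, n_R, phi))
      }
    )$gamma
  } else 1
  structure(list(gamma_L = gamma_L, gamma_R = gamma_R),
            class = "gamma_thresholds")
}

#' Trial-level safety check
#'
#' A dose is deemed overly toxic when `Pr(p > phi | y, n) > cutoff` under the
#' beta-binomial posterior with prior `Beta(phi, 1 - phi)`. Applied to the
#' lowest dose it terminates the trial; applied to any dose it eliminates
#' that dose and all higher doses.
#'
#' @param y1 DLT count at the dose.
#' @param n1 treated count at the dose (0 means no evidence: continue).
#' @param phi target DLT rate.
#' @param cutoff posterior probability threshold (default 0.95).
#' @return `"terminate"` or `"continue"`.
#' @export
check_safety <- function(y1, n1, phi, cutoff = 0.95) {
  stopifnot(y1 >= 0, y1 <= n1)
  if (n1 == 0) return("continue")
  pr <- 1 - stats::pbeta(phi, phi + y1, 1 - phi + n1 - y1)
  if (pr > cutoff) "terminate" else "continue"
}

#' Doses eliminated for excessive toxicity
#'
#' Applies the [check_safety()] rule to every tested dose; an over-toxic
#' dose is eliminated together with all higher doses (upward-closed set).
#'
#' @param y_k,n_k per-dose DLT and treatment counts.
#' @param phi target DLT rate.
#' @param cutoff posterior probability threshold (default 0.95).
#' @return integer vector of eliminated dose indices (possibly empty).
#' @export
eliminated_doses <- function(y_k, n_k, phi, cutoff = 0.95) {
  K <- length(n_k)
  for (k in seq_len(K)) {
    if (n_k[k] > 0 &&
        check_safety(y_k[k], n_k[k], phi, cutoff) == "terminate") {
      return(k:K)
    }
  }
  integer(0)
}

# Weighted pool-adjacent-violators algorithm for isotonic (non-decreasing)
# weighted least squares.
pava <- function(x, w) {
  n <- length(x)
  if (n <= 1) return(x)
  val <- x
  wt <- w
  lev <- as.list(seq_len(n))
  i <- 1
  while (i < length(val)) {
    if (val[i] > val[i + 1] + 1e-12) {
      nw <- wt[i] + wt[i + 1]
      nv <- (val[i] * wt[i] + val[i + 1] * wt[i + 1]) / nw
      val <- c(val[seq_len(i - 1)], nv, val[-seq_len(i + 1)])
      wt <- c(wt[seq_len(i - 1)], nw, wt[-seq_len(i + 1)])
      lev[[i]] <- c(lev[[i]], lev[[i + 1]])
      lev[[i + 1]] <- NULL
      i <- max(i - 1, 1)
    } else {
      i <- i + 1
    }
  }
  out <- numeric(n)
  for (j in seq_along(val)) out[lev[[j]]] <- val[j]
  out
}

#' Final MTD selection by isotonic regression
#'
#' Pool-adjacent-violators isotonic estimates of the per-dose DLT rates
#' `y_k / n_k` (weights `n_k`, untested doses excluded) are compared with
#' the target; the tested, non-eliminated dose whose estimate is closest to
#' `phi` is selected. Ties are broken toward the lower dose when the tied
#' estimates exceed `phi` (safety) and toward the higher dose when below it,
#' with exact ties at `phi` resolved to the lower dose.
#'
#' @param y_k,n_k per-dose DLT and treatment counts.
#' @param phi target DLT rate.
#' @param eliminated integer vector of eliminated dose indices.
#' @return selected dose index, or `NA_integer_` when no dose is selectable.
#' @examples
#' select_mtd(c(0, 1, 2), c(3, 3, 3), phi = 0.33) # dose 2
#' @export
select_mtd <- function(y_k, n_k, phi, eliminated = integer(0)) {
  tested <- which(n_k > 0)
  cand <- setdiff(tested, eliminated)
  if (length(cand) == 0) return(NA_integer_)
  iso <- rep(NA_real_, length(n_k))
  iso[tested] <- pava(y_k[tested] / n_k[tested], n_k[tested])
  # tiny increasing jitter implements the tie-break convention above
  dist <- abs(iso[cand] + cand * 1e-10 - phi)
  cand[which.min(dist)]
}
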