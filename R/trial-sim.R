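#' Trial design configuration
#'
#' Bundles the design parameters of a simulated dose-finding trial:
#' target rate, dose count, cohort size, effective-sample-size caps, timing
#' parameters, the allocation scheme, and the decision engine.
#'
#' @param phi target DLT rate.
#' @param n_doses number of dose levels.
#' @param max_effective trial stops once this many effective patients
#'   (treatment cycles) have been assigned (default 24).
#' @param per_dose_cap trial stops once any dose has accumulated this many
#'   effective patients (default 12); `Inf` disables the per-dose rule.
#' @param cohort_size patients per cohort (default 3).
#' @param start_dose dose for the first cohort (default 1).
#' @param elimination_cutoff posterior probability cutoff for dose
#'   elimination (default 0.95).
#' @param stop_cutoff cutoff for early termination at the lowest dose
#'   (default 0.95).
#' @param assessment_weeks DLT assessment window (default 3).
#' @param interarrival_weeks weeks between patient arrivals (default 2).
#' @param max_cycles maximum treatment cycles per patient (default 3).
#' @param scheme allocation scheme: `"pride"`, `"pride_fa"`, `"aide"`,
#'   `"ipde"`, or `"cfo_standard"` (no retreatment).
#' @param engine decision engine: `"cfo"`, `"boin"`, or `"crm"`.
#' @param n_posterior posterior draws per decision (default 2000).
#' @param burnin sampler burn-in (default equals `n_posterior`).
#' @param correlated_outcomes generate outcomes with true patient random
#'   effects (default `FALSE`: independent Bernoulli draws at the scenario's
#'   marginal probabilities).
#' @param sigma2_true true random-effect variance in correlated mode.
#' @param min_washout_weeks minimum washout before retreatment (default 0).
#' @return object of class `design_config`.
#' @export
design_config <- function(phi, n_doses, max_effective = 24,
                          per_dose_cap = 12, cohort_size = 3,
                          start_dose = 1, elimination_cutoff = 0.95,
                          stop_cutoff = 0.95, assessment_weeks = 3,
                          interarrival_weeks = 2, max_cycles = 3,
                          scheme = c("pride", "pride_fa", "aide", "ipde",
                                     "cfo_standard"),
                          engine = c("cfo", "boin", "crm"),
                          n_posterior = 2000, burnin = n_posterior,
                          correlated_outcomes = FALSE, sigma2_true = 1,
                          min_washout_weeks = 0) {
  scheme <- match.arg(scheme)
  engine <- match.arg(engine)
  stopifnot(phi > 0, phi < 1, n_doses >= 2, max_effective >= cohort_size,
            cohort_size >= 1, start_dose >= 1, start_dose <= n_doses,
            max_cycles >= 1)
  structure(
    list(phi = phi, n_doses = as.integer(n_doses),
         max_effective = max_effective, per_dose_cap = per_dose_cap,
         cohort_size = as.integer(cohort_size),
         start_dose = as.integer(start_dose),
         elimination_cutoff = elimination_cutoff, stop_cutoff = stop_cutoff,
         assessment_weeks = assessment_weeks,
         interarrival_weeks = interarrival_weeks,
         max_cycles = as.integer(max_cycles),
         scheme = scheme, engine = engine,
         n_posterior = as.integer(n_posterior), burnin = as.integer(burnin),
         correlated_outcomes = correlated_outcomes,
         sigma2_true = sigma2_true,
         min_washout_weeks = min_washout_weeks),
    class = "design_config"
  )
}

#' Simulate one DLT outcome
#'
#' Bernoulli draw at the scenario's marginal dose probability, or --- in
#' correlated mode --- at `plogis(qlogis(p) + W_i)` for a patient effect
#' `W_i`.
#'
#' @param true_probs true per-dose DLT probabilities.
#' @param patient_effect patient random effect (ignored when NULL/0).
#' @param dose dose index.
#' @param u uniform(0,1) variate driving the draw (one per patient-cycle).
#' @return 0 or 1.
#' @export
simulate_outcome <- function(true_probs, patient_effect, dose, u) {
  p <- true_probs[dose]
  if (!is.null(patient_effect) && patient_effect != 0 && p > 0 && p < 1) {
    p <- stats::plogis(stats::qlogis(p) + patient_effect)
  }
  as.integer(u < p)
}

# Build a trial_data object from the patient pool (observed outcomes only).
pool_to_trial_data <- function(pool, n_doses) {
  n <- length(pool)
  y <- matrix(NA_real_, n, n_doses)
  tr <- matrix(0L, n, n_doses)
  zt <- matrix(1L, n, n_doses)
  for (i in seq_len(n)) {
    h <- pool[[i]]$history
    obs <- which(!is.na(h$outcome))
    for (r in obs) {
      tr[i, h$dose[r]] <- 1L
      y[i, h$dose[r]] <- h$outcome[r]
      zt[i, h$dose[r]] <- h$z[r]
    }
  }
  trial_data(y, tr, zt)
}

# memoized gamma thresholds
.gamma_cache <- new.env(parent = emptyenv())
cached_gammas <- function(n_L, n_C, n_R, phi) {
  key <- paste(n_L, n_C, n_R, phi, sep = "|")
  if (is.null(.gamma_cache[[key]])) {
    .gamma_cache[[key]] <- calibrate_gammas(n_L, n_C, n_R, phi)
  }
  .gamma_cache[[key]]
}

# Decision epoch: fit the scheme's model on observed data and return the
# dose for the next cohort (bounded, respecting eliminations).
decide_next_dose <- function(pool, current, config, priors) {
  K <- config$n_doses
  data <- pool_to_trial_data(pool, K)
  tot <- dose_totals(data)
  y_k <- tot$y_k
  n_k <- tot$n_k

  elim <- eliminated_doses(y_k, n_k, config$phi, config$elimination_cutoff)
  if (1L %in% elim) {
    return(list(dose = NA_integer_, eliminated = elim, terminated = TRUE,
                move = "terminate", y_k = y_k, n_k = n_k))
  }

  if (config$engine == "cfo") {
    if (config$scheme == "cfo_standard") {
      odds <- compute_odds_counts(y_k, n_k, current, config$phi)
    } else {
      re <- !(config$scheme %in% c("aide", "ipde"))
      draws <- sample_posterior(data, priors,
                                scheme = if (config$scheme == "pride_fa")
                                  "pride_fa" else "pride",
                                n_samples = config$n_posterior,
                                burnin = config$burnin,
                                random_effects = re)
      odds <- compute_odds(posterior_dose_rates(draws), current, config$phi)
    }
    gm <- cached_gammas(if (current > 1) n_k[current - 1] else 0,
                        n_k[current],
                        if (current < K) n_k[current + 1] else 0,
                        config$phi)
    move <- cfo_decide(odds, gm)
  } else if (config$engine == "boin") {
    if (config$scheme == "cfo_standard") {
      est <- if (n_k[current] > 0) y_k[current] / n_k[current] else 0
    } else {
      re <- !(config$scheme %in% c("aide", "ipde"))
      draws <- sample_posterior(data, priors,
                                scheme = if (config$scheme == "pride_fa")
                                  "pride_fa" else "pride",
                                n_samples = config$n_posterior,
                                burnin = config$burnin,
                                random_effects = re)
      est <- mean(posterior_dose_rates(draws)[, current])
    }
    move <- boin_decide(est, boin_boundaries(config$phi))
  } else { # crm
    re <- !(config$scheme %in% c("aide", "ipde", "cfo_standard"))
    fit <- crm_random_effects(data, priors$c, config$phi,
                              eta = priors$eta,
                              n_samples = config$n_posterior,
                              burnin = config$burnin,
                              random_effects = re)
    move <- if (fit$next_dose > current) "escalate"
            else if (fit$next_dose < current) "de_escalate" else "stay"
  }

  dose <- current
  if (move == "escalate") {
    cand <- current + 1L
    if (cand <= K && !(cand %in% elim)) dose <- cand
  } else if (move == "de_escalate") {
    dose <- max(current - 1L, 1L)
  }
  if (dose %in% elim) dose <- max(setdiff(seq_len(dose), elim))
  list(dose = dose, eliminated = elim, terminated = FALSE, move = move,
       y_k = y_k, n_k = n_k)
}

#' Simulate a complete dose-finding trial
#'
#' Discrete-event simulation at weekly granularity. Patients arrive every
#' `interarrival_weeks` (patient j at week `1 + (j-1) * interarrival`); the
#' first cohort is treated at the start dose as soon as all members have
#' arrived. Each subsequent cohort's dose is decided when the previous
#' cohort's assessment window closes, using the scheme's fitted model and
#' the engine's decision rule, after applying the dose-elimination and
#' early-termination checks. Cohort slots are filled by [form_cohort()];
#' cohort members start treatment simultaneously once all are available.
#' The trial stops when the number of assigned effective patients reaches
#' `max_effective`, when any dose accumulates `per_dose_cap` effective
#' patients, or on early termination; the MTD is then chosen by
#' [select_mtd()] on the pooled per-dose counts.
#'
#' @param scn a [scenario].
#' @param config a [design_config] (its `phi`/`n_doses` must match the
#'   scenario).
#' @param priors a [hier_priors] object.
#' @param seed integer seed; the whole trial is reproducible given it.
#' @param outcome_u optional pre-drawn uniform matrix (patients x cycles)
#'   driving DLT outcomes; used for common-random-numbers pairing across
#'   schemes. Drawn internally when NULL.
#' @return object of class `trial_result`: list with `selected_dose`
#'   (NA when none), `y_k`, `n_k` (pooled per-dose counts),
#'   `effective_patients`, `distinct_patients`, `duration_weeks`,
#'   `dlt_count`, `terminated_early`, `eliminated`, `ledger` (per-cycle
#'   data.frame) and `decisions` (per-epoch trace).
#' @export
run_trial <- function(scn, config, priors, seed = NULL, outcome_u = NULL) {
  stopifnot(inherits(scn, "scenario"), inherits(config, "design_config"),
            length(scn$probs) == config$n_doses)
  if (!is.null(seed)) set.seed(seed)
  K <- config$n_doses
  n_max <- ceiling(config$max_effective + config$cohort_size + 8)
  if (is.null(outcome_u)) {
    outcome_u <- matrix(stats::runif(n_max * config$max_cycles),
                        n_max, config$max_cycles)
  }
  w_true <- if (config$correlated_outcomes) {
    stats::rnorm(nrow(outcome_u), 0, sqrt(config$sigma2_true))
  } else {
    rep(0, nrow(outcome_u))
  }

  arrival <- function(j) 1 + (j - 1) * config$interarrival_weeks
  pool <- list()
  enrolled <- 0L

  current <- config$start_dose
  eliminated <- integer(0)
  terminated <- FALSE
  assigned <- 0
  assigned_dose <- numeric(K)
  decision_week <- 0
  last_end <- 0
  decisions <- list()
  cohort <- 0L
  eff_cycles <- if (config$scheme == "cfo_standard") 1L else config$max_cycles

  repeat {
    cohort <- cohort + 1L
    if (cohort > 1L) {
      dec <- decide_next_dose(pool, current, config, priors)
      eliminated <- union(eliminated, dec$eliminated)
      decisions[[cohort - 1L]] <- data.frame(
        cohort = cohort - 1L, week = decision_week, current_dose = current,
        move = dec$move, next_dose = ifelse(is.na(dec$dose), NA, dec$dose))
      if (dec$terminated) {
        terminated <- TRUE
        break
      }
      current <- dec$dose
    }

    # patients arrive continuously; everyone arrived by now is enrolled
    while (arrival(enrolled + 1L) <= decision_week) {
      enrolled <- enrolled + 1L
      pool[[enrolled]] <- patient_record(enrolled, arrival(enrolled))
    }

    asg <- form_cohort(current, pool, week = decision_week,
                       cohort_size = config$cohort_size,
                       scheme = if (config$scheme == "cfo_standard") "pride"
                                else config$scheme,
                       n_doses = K, eliminated = eliminated,
                       max_cycles = eff_cycles,
                       min_washout_weeks = config$min_washout_weeks)
    # shortfall: enroll the next patients in the arrival sequence
    idx <- asg$patient
    for (r in which(asg$source == "new")) {
      enrolled <- enrolled + 1L
      if (enrolled > nrow(outcome_u)) {
        stop("outcome stream exhausted; enlarge outcome_u")
      }
      pool[[enrolled]] <- patient_record(enrolled, arrival(enrolled))
      idx[r] <- enrolled
    }
    avail <- vapply(seq_len(nrow(asg)), function(r) {
      p <- pool[[idx[r]]]
      if (nrow(p$history) == 0) p$arrival_week else max(p$history$end_week)
    }, numeric(1))
    start_week <- max(decision_week, max(avail))
    end_week <- start_week + config$assessment_weeks

    for (r in seq_len(nrow(asg))) {
      i <- idx[r]
      cyc <- n_cycles(pool[[i]]) + 1L
      u <- outcome_u[i, cyc]
      out <- simulate_outcome(scn$probs, w_true[i], asg$dose[r], u)
      pool[[i]] <- add_cycle(pool[[i]], asg$dose[r], start_week, end_week,
                             out, asg$z[r])
      assigned <- assigned + 1
      assigned_dose[asg$dose[r]] <- assigned_dose[asg$dose[r]] + 1
    }
    last_end <- end_week
    decision_week <- end_week

    if (assigned >= config$max_effective) break
    if (any(assigned_dose >= config$per_dose_cap)) break
  }

  data <- pool_to_trial_data(pool, K)
  tot <- dose_totals(data)
  # final elimination update from complete data
  if (!terminated) {
    eliminated <- union(eliminated,
                        eliminated_doses(tot$y_k, tot$n_k, config$phi,
                                         config$elimination_cutoff))
    if (1L %in% eliminated) terminated <- TRUE
  }
  selected <- if (terminated) NA_integer_ else {
    select_mtd(tot$y_k, tot$n_k, config$phi, eliminated)
  }
  ledger <- patient_ledger(pool)
  treated_ids <- unique(ledger$id)
  structure(
    list(selected_dose = selected, y_k = tot$y_k, n_k = tot$n_k,
         effective_patients = sum(tot$n_k),
         distinct_patients = length(treated_ids),
         duration_weeks = last_end,
         dlt_count = sum(tot$y_k),
         terminated_early = terminated,
         eliminated = sort(eliminated),
         ledger = ledger,
         decisions = if (length(decisions)) do.call(rbind, decisions)
                     else NULL),
    class = "trial_result"
  )
}

#' @export
print.trial_result <- function(x, ...) {
  cat("trial_result: selected dose",
      ifelse(is.na(x$selected_dose), "none", x$selected_dose),
      "|", x$distinct_patients, "patients,",
      x$effective_patients, "effective |",
      x$duration_weeks, "weeks",
      if (x$terminated_early) "| terminated early" else "", "\n")
  cat("  DLTs/treated per dose:",
      paste(sprintf("%d/%d", x$y_k, x$n_k), collapse = " "), "\n")
  invisible(x)
}

#' Replicated operating-characteristic study
#'
#' Runs `n_reps` independent trials per scenario (replication r uses seed
#' `base_seed + r`) and aggregates the operating characteristics with
#' [aggregate_oc()]. When `baseline_config` is supplied, a paired baseline
#' trial is run on each replication with the same pre-drawn outcome stream
#' (common random numbers), enabling the sample-size-reduction metric.
#'
#' @param scenarios list of [scenario] objects.
#' @param config a [design_config].
#' @param priors a [hier_priors].
#' @param n_reps replications per scenario.
#' @param base_seed integer seed offset.
#' @param baseline_config optional [design_config] for the paired baseline
#'   (typically the standard no-retreatment design).
#' @return list with `metrics` (one data.frame row per scenario) and
#'   `results` (per-scenario lists of `trial_result`s).
#' @export
run_oc <- function(scenarios, config, priors, n_reps, base_seed = 1,
                   baseline_config = NULL) {
  all_metrics <- list()
  all_results <- list()
  for (s in seq_along(scenarios)) {
    scn <- scenarios[[s]]
    res <- vector("list", n_reps)
    base <- if (!is.null(baseline_config)) vector("list", n_reps) else NULL
    for (r in seq_len(n_reps)) {
      seed <- base_seed + (s - 1L) * n_reps + r
      set.seed(seed)
      n_max <- ceiling(config$max_effective + config$cohort_size + 8)
      u <- matrix(stats::runif(n_max * config$max_cycles),
                  n_max, config$max_cycles)
      res[[r]] <- run_trial(scn, config, priors, seed = seed, outcome_u = u)
      if (!is.null(baseline_config)) {
        set.seed(seed)
        invisible(stats::runif(n_max * config$max_cycles))
        base[[r]] <- run_trial(scn, baseline_config, priors, seed = NULL,
                               outcome_u = u)
      }
    }
    all_results[[scn$label]] <- res
    all_metrics[[scn$label]] <- aggregate_oc(res, scn, base)
  }
  list(metrics = do.call(rbind, all_metrics), results = all_results)
}
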