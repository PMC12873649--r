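fast_config <- function(...) {
  design_config(phi = 0.33, n_doses = 5, n_posterior = 200, ...)
}
pri5 <- function() hier_priors(5)

test_that("design configuration validates its arguments", {
  cfg <- fast_config()
  expect_s3_class(cfg, "design_config")
  expect_equal(cfg$scheme, "pride")
  expect_equal(cfg$engine, "cfo")
  expect_error(design_config(phi = 0.33, n_doses = 1))
  expect_error(design_config(phi = 0.33, n_doses = 5, start_dose = 6))
  expect_error(design_config(phi = 0.33, n_doses = 5, scheme = "bogus"))
})

test_that("outcome simulation thresholds the uniform draw", {
  p <- c(0.1, 0.4)
  expect_equal(simulate_outcome(p, 0, 1, 0.05), 1L)
  expect_equal(simulate_outcome(p, 0, 1, 0.15), 0L)
  expect_equal(simulate_outcome(p, 0, 2, 0.39), 1L)
  # positive patient effect raises the threshold: same u can flip to DLT
  p_shift <- plogis(qlogis(0.4) + 1)
  expect_equal(simulate_outcome(p, 1, 2, p_shift - 1e-6), 1L)
  expect_equal(simulate_outcome(p, 1, 2, p_shift + 1e-6), 0L)
  # degenerate probabilities are untouched by the effect
  expect_equal(simulate_outcome(c(0, 1), 5, 1, 0.5), 0L)
  expect_equal(simulate_outcome(c(0, 1), -5, 2, 0.5), 1L)
})

test_that("pool conversion keeps only assessed cycles", {
  p1 <- patient_record(1, 0)
  p1 <- add_cycle(p1, 1, 0, 3, 0, 1L)
  p1 <- add_cycle(p1, 2, 3, 6, NA, 1L) # pending
  p2 <- patient_record(2, 2)
  d <- pool_to_trial_data(list(p1, p2), 3)
  expect_equal(sum(d$treated), 1L)
  expect_equal(d$treated[1, ], c(1L, 0L, 0L))
})

test_that("trials are reproducible from the seed", {
  scn <- fixed_scenarios("A")[[2]]
  cfg <- fast_config()
  a <- run_trial(scn, cfg, pri5(), seed = 101)
  b <- run_trial(scn, cfg, pri5(), seed = 101)
  expect_identical(a$selected_dose, b$selected_dose)
  expect_identical(a$ledger, b$ledger)
  expect_identical(a$duration_weeks, b$duration_weeks)
})

test_that("trial results satisfy structural invariants", {
  pri <- pri5()
  set.seed(500)
  scns <- fixed_scenarios("A")
  for (rep in 1:8) {
    scn <- scns[[sample.int(5, 1)]]
    scheme <- sample(c("pride", "pride_fa", "aide", "ipde", "cfo_standard"),
                     1)
    cfg <- fast_config(scheme = scheme)
    res <- run_trial(scn, cfg, pri, seed = 1000 + rep)
    # accounting: ledger rows = assessed effective patients = sum of n_k
    expect_equal(nrow(res$ledger), sum(res$n_k))
    expect_equal(res$effective_patients, sum(res$n_k))
    expect_lte(res$distinct_patients, res$effective_patients)
    expect_equal(res$dlt_count, sum(res$y_k))
    expect_true(all(res$y_k <= res$n_k))
    # stopping rule: cap reached (within one cohort of slack) or terminated
    expect_true(res$terminated_early ||
                  res$effective_patients >= cfg$max_effective ||
                  max(res$n_k) >= cfg$per_dose_cap)
    expect_lte(res$effective_patients,
               cfg$max_effective + cfg$cohort_size - 1)
    # selection: a tested, non-eliminated dose (or NA on termination)
    if (!is.na(res$selected_dose)) {
      expect_gt(res$n_k[res$selected_dose], 0)
      expect_false(res$selected_dose %in% res$eliminated)
    } else {
      expect_true(res$terminated_early)
    }
    # per-patient: no dose repeated, at most max_cycles cycles
    cyc <- table(res$ledger$id)
    expect_true(all(cyc <= cfg$max_cycles))
    for (id in unique(res$ledger$id)) {
      h <- res$ledger[res$ledger$id == id, ]
      expect_equal(anyDuplicated(h$dose), 0L)
      expect_true(all(diff(h$start_week) > 0))
      # a DLT ends the patient's participation
      if (any(h$outcome == 1)) {
        expect_equal(which(h$outcome == 1), nrow(h))
      }
    }
    # no retreatment in the standard design
    if (scheme == "cfo_standard") expect_true(all(cyc == 1))
    # up-only schemes never revisit a lower dose within a patient
    if (scheme %in% c("pride", "aide")) {
      for (id in unique(res$ledger$id)) {
        h <- res$ledger[res$ledger$id == id, ]
        expect_true(all(diff(h$dose) > 0))
        expect_true(all(h$z == 1L))
      }
    }
    # duration equals the close of the last assessment window
    expect_equal(res$duration_weeks, max(res$ledger$end_week))
    # dose path moves one step at a time
    if (!is.null(res$decisions)) {
      moved <- res$decisions$next_dose - res$decisions$current_dose
      expect_true(all(abs(moved[!is.na(moved)]) <= 1))
    }
  }
})

test_that("an over-toxic trial terminates without selecting a dose", {
  # extreme toxicity at every dose: termination should be near-certain,
  # and a terminated trial must never report an MTD
  scn <- scenario(c(0.8, 0.85, 0.9, 0.95, 0.99), 0.33, label = "hot")
  cfg <- fast_config()
  hits <- vapply(1:10, function(r) {
    res <- run_trial(scn, cfg, pri5(), seed = 3000 + r)
    if (res$terminated_early) expect_true(is.na(res$selected_dose))
    res$terminated_early && is.na(res$selected_dose)
  }, logical(1))
  expect_gt(mean(hits), 0.8)
})

test_that("paired replications share the outcome stream", {
  scn <- fixed_scenarios("A")[[2]]
  cfg <- fast_config(scheme = "pride")
  base_cfg <- fast_config(scheme = "cfo_standard")
  oc <- run_oc(list(scn), cfg, pri5(), n_reps = 3, base_seed = 7,
               baseline_config = base_cfg)
  expect_s3_class(oc$metrics, "data.frame")
  expect_equal(oc$metrics$n_reps, 3)
  expect_false(is.na(oc$metrics$sample_size_reduction_pct))
  # same seed, same u: first-cohort outcomes at the start dose must agree
  set.seed(8)
  u <- matrix(runif(35 * 3), 35, 3)
  r1 <- run_trial(scn, cfg, pri5(), seed = 99, outcome_u = u)
  r2 <- run_trial(scn, base_cfg, pri5(), seed = 99, outcome_u = u)
  h1 <- r1$ledger[r1$ledger$id %in% 1:3 & r1$ledger$cycle == 1, ]
  h2 <- r2$ledger[r2$ledger$id %in% 1:3 & r2$ledger$cycle == 1, ]
  expect_equal(h1$outcome, h2$outcome)
})

test_that("alternative engines run end to end", {
  scn <- fixed_scenarios("A")[[2]]
  pri <- pri5()
  for (eng in c("boin", "crm")) {
    cfg <- fast_config(scheme = "pride", engine = eng)
    res <- run_trial(scn, cfg, pri, seed = 11)
    expect_s3_class(res, "trial_result")
    expect_equal(nrow(res$ledger), sum(res$n_k))
  }
  # correlated outcome mode
  cfg <- fast_config(correlated_outcomes = TRUE, sigma2_true = 1)
  res <- run_trial(scn, cfg, pri, seed = 13)
  expect_s3_class(res, "trial_result")
})
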