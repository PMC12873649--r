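#' Highest-dose-matter patient counting
#'
#' Each distinct patient is counted once, at the highest dose level they
#' received across all their treatment cycles. A patient treated at doses
#' 1, 2 and 3 with MTD 2 therefore contributes to overdose allocation and
#' not to MTD allocation.
#'
#' @param result a `trial_result` from [run_trial()].
#' @return integer vector of per-dose distinct-patient counts (sums to the
#'   trial's distinct-patient total).
#' @export
patient_counting <- function(result) {
  stopifnot(inherits(result, "trial_result"))
  K <- length(result$n_k)
  counts <- integer(K)
  if (nrow(result$ledger) > 0) {
    top <- tapply(result$ledger$dose, result$ledger$id, max)
    tb <- table(factor(top, levels = seq_len(K)))
    counts <- as.integer(tb)
  }
  counts
}

pct_se <- function(p_hat, n) 100 * sqrt(p_hat * (1 - p_hat) / n)

#' Aggregate operating characteristics over replications
#'
#' Computes the accuracy, safety and efficiency summaries of a replicated
#' simulation: per-dose and none selection percentages, MTD/overdose
#' selection, MTD/overdose allocation under highest-dose-matter counting,
#' mean per-dose effective patients (raw treatment-cycle counts), mean
#' distinct patients, mean trial duration, and --- when paired baseline
#' results are supplied --- the sample-size reduction
#' `100 (mean distinct patients baseline - scheme) / baseline`, with
#' Monte-Carlo standard errors for the percentages.
#'
#' @param results list of `trial_result`s for the scheme under study.
#' @param scn the [scenario] the trials were run on.
#' @param baseline_results optional list of `trial_result`s from a baseline
#'   design on matched replications (required for sample-size reduction,
#'   which is reported as NA when absent).
#' @return one-row data.frame of class `operating_characteristics`.
#' @export
aggregate_oc <- function(results, scn, baseline_results = NULL) {
  R <- length(results)
  stopifnot(R >= 1)
  K <- length(results[[1]]$n_k)
  sel <- vapply(results, function(x) x$selected_dose, integer(1))
  sel_pct <- 100 * vapply(seq_len(K),
                          function(k) mean(!is.na(sel) & sel == k),
                          numeric(1))
  none_pct <- 100 * mean(is.na(sel))
  mtd <- scn$mtd_index
  if (!is.na(mtd)) {
    mtd_sel <- sel_pct[mtd]
    over_sel <- 100 * mean(!is.na(sel) & sel > mtd)
  } else {
    mtd_sel <- NA_real_
    over_sel <- 100 * mean(!is.na(sel)) # every dose exceeds the target
  }

  alloc <- vapply(results, patient_counting, integer(K))
  if (K == 1) alloc <- matrix(alloc, nrow = 1)
  tot_pat <- sum(alloc)
  if (!is.na(mtd) && tot_pat > 0) {
    mtd_alloc <- 100 * sum(alloc[mtd, ]) / tot_pat
    over_alloc <- if (mtd < K) 100 * sum(alloc[(mtd + 1):K, ]) / tot_pat
                  else 0
  } else {
    mtd_alloc <- NA_real_
    over_alloc <- if (tot_pat > 0) 100 else NA_real_
  }

  n_k_mat <- vapply(results, function(x) x$n_k, integer(K))
  if (K == 1) n_k_mat <- matrix(n_k_mat, nrow = 1)
  distinct <- vapply(results, function(x) x$distinct_patients, integer(1))
  duration <- vapply(results, function(x) x$duration_weeks, numeric(1))

  reduction <- NA_real_
  if (!is.null(baseline_results)) {
    base_distinct <- vapply(baseline_results,
                            function(x) x$distinct_patients, integer(1))
    reduction <- 100 * (mean(base_distinct) - mean(distinct)) /
      mean(base_distinct)
  }

  out <- data.frame(
    scenario = scn$label, n_reps = R,
    mtd_selection_pct = mtd_sel,
    mtd_selection_se = if (is.na(mtd_sel)) NA_real_
                       else pct_se(mtd_sel / 100, R),
    overdose_selection_pct = over_sel,
    overdose_selection_se = pct_se(over_sel / 100, R),
    none_selected_pct = none_pct,
    mtd_allocation_pct = mtd_alloc,
    overdose_allocation_pct = over_alloc,
    sample_size_reduction_pct = reduction,
    mean_distinct_patients = mean(distinct),
    mean_effective_patients = mean(vapply(results, function(x)
      x$effective_patients, integer(1))),
    mean_duration_weeks = mean(duration)
  )
  for (k in seq_len(K)) {
    out[[paste0("select_d", k, "_pct")]] <- sel_pct[k]
    out[[paste0("mean_n_d", k)]] <- mean(n_k_mat[k, ])
  }
  class(out) <- c("operating_characteristics", "data.frame")
  out
}
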