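#' Patient record
#'
#' One enrolled subject: identifier, arrival week and treatment history.
#' Each history row is one treatment cycle with its dose, start and
#' assessment-end weeks, outcome (0/1, or NA while the assessment is
#' pending) and assignment type `z` (1 = new or up-retreated, 2 =
#' down-retreated).
#'
#' @param id integer identifier (enrollment order).
#' @param arrival_week non-negative arrival week.
#' @return object of class `patient_record`.
#' @export
patient_record <- function(id, arrival_week) {
  structure(
    list(id = as.integer(id), arrival_week = arrival_week,
         history = data.frame(dose = integer(), start_week = numeric(),
                              end_week = numeric(), outcome = integer(),
                              z = integer())),
    class = "patient_record"
  )
}

#' @export
print.patient_record <- function(x, ...) {
  cat("patient", x$id, "(arrived week", x$arrival_week, "):",
      nrow(x$history), "cycle(s)\n")
  if (nrow(x$history)) print(x$history)
  invisible(x)
}

# Append a treatment cycle to a patient record.
add_cycle <- function(p, dose, start_week, end_week, outcome, z = 1L) {
  if (dose %in% p$history$dose) {
    stop("patient ", p$id, " already treated at dose ", dose)
  }
  p$history <- rbind(p$history,
                     data.frame(dose = as.integer(dose),
                                start_week = start_week,
                                end_week = end_week,
                                outcome = as.integer(outcome),
                                z = as.integer(z)))
  p
}

had_dlt <- function(p) {
  any(!is.na(p$history$outcome) & p$history$outcome == 1L)
}

has_pending <- function(p) any(is.na(p$history$outcome))

n_cycles <- function(p) nrow(p$history)

#' Retreatment eligibility
#'
#' A patient is eligible for retreatment when they have experienced no DLT,
#' have completed fewer than `max_cycles` treatment cycles, and have no
#' assessment still pending.
#'
#' @param p a [patient_record].
#' @param max_cycles maximum treatment cycles per patient (default 3).
#' @return logical.
#' @export
eligible_for_retreat <- function(p, max_cycles = 3L) {
  stopifnot(inherits(p, "patient_record"))
  n_cycles(p) > 0 && !had_dlt(p) && !has_pending(p) &&
    n_cycles(p) < max_cycles
}

#' Doses a retreated patient may receive
#'
#' Scheme-specific allocation restriction, given the trial-level dose chosen
#' for the next cohort:
#' * `pride`, `aide`: only the trial dose, and only if it is strictly higher
#'   than every dose the patient already received (up-only retreatment);
#' * `pride_fa`: the trial dose at any level, as long as the patient has not
#'   already received it (one observation per patient per dose);
#' * `ipde`: the patient's own next-higher dose regardless of trial movement,
#'   capped at the highest non-eliminated dose.
#'
#' @param p a [patient_record].
#' @param next_dose trial-level dose for the upcoming cohort.
#' @param scheme one of `"pride"`, `"pride_fa"`, `"aide"`, `"ipde"`.
#' @param n_doses number of dose levels.
#' @param eliminated integer vector of eliminated doses.
#' @return integer vector of allowed doses (length 0 or 1).
#' @export
allowed_doses <- function(p, next_dose, scheme, n_doses,
                          eliminated = integer(0)) {
  stopifnot(inherits(p, "patient_record"))
  hist_doses <- p$history$dose
  if (scheme %in% c("pride", "aide")) {
    if (length(hist_doses) == 0 || next_dose > max(hist_doses)) {
      return(as.integer(next_dose))
    }
    return(integer(0))
  }
  if (scheme == "pride_fa") {
    if (!(next_dose %in% hist_doses)) return(as.integer(next_dose))
    return(integer(0))
  }
  if (scheme == "ipde") {
    own <- if (length(hist_doses) == 0) next_dose else max(hist_doses) + 1L
    cap <- max(setdiff(seq_len(n_doses), eliminated))
    own <- min(own, cap)
    if (own %in% hist_doses || own > n_doses) return(integer(0))
    return(as.integer(own))
  }
  stop("unknown scheme: ", scheme)
}

#' Form the next treatment cohort
#'
#' Fills `cohort_size` slots in priority order: (1) patients already
#' enrolled but never treated, (2) eligible retreated patients ordered by
#' longest elapsed time since the end of their last treatment (ties go to
#' the earlier-enrolled patient), subject to the scheme's
#' [allowed_doses()] restriction, and (3) newly enrolled patients. Each
#' assignment carries the dose and the assignment type `z` (2 when a
#' retreated patient receives a dose below their previous maximum, under
#' flexible allocation).
#'
#' @param next_dose trial-level dose for the cohort.
#' @param pool list of [patient_record]s currently in the trial.
#' @param week decision week (used for elapsed-time ordering).
#' @param cohort_size number of slots (default 3).
#' @param scheme allocation scheme (see [allowed_doses()]).
#' @param n_doses number of dose levels.
#' @param eliminated integer vector of eliminated doses.
#' @param max_cycles maximum cycles per patient (default 3).
#' @param min_washout_weeks minimum weeks since last treatment end before a
#'   retreat (default 0: priority ordering only).
#' @return data.frame with one row per slot: `slot`, `source`
#'   (`"untreated"`, `"retreat"`, `"new"`), `patient` (pool index, NA for a
#'   new enrollee), `dose`, `z`.
#' @export
form_cohort <- function(next_dose, pool, week, cohort_size = 3L,
                        scheme = "pride", n_doses, eliminated = integer(0),
                        max_cycles = 3L, min_washout_weeks = 0) {
  assignments <- data.frame(slot = integer(), source = character(),
                            patient = integer(), dose = integer(),
                            z = integer())
  take <- function(source, patient, dose, z) {
    rbind(assignments,
          data.frame(slot = nrow(assignments) + 1L, source = source,
                     patient = patient, dose = as.integer(dose),
                     z = as.integer(z)))
  }
  # (1) enrolled, never treated
  untreated <- which(vapply(pool, function(p) {
    n_cycles(p) == 0 && p$arrival_week <= week
  }, logical(1)))
  for (i in untreated) {
    if (nrow(assignments) >= cohort_size) break
    assignments <- take("untreated", i, next_dose, 1L)
  }
  # (2) eligible retreats, longest washout first
  if (nrow(assignments) < cohort_size) {
    elig <- which(vapply(pool, function(p) {
      eligible_for_retreat(p, max_cycles) &&
        (week - max(p$history$end_week)) >= min_washout_weeks
    }, logical(1)))
    if (length(elig)) {
      last_end <- vapply(pool[elig], function(p) max(p$history$end_week),
                         numeric(1))
      ids <- vapply(pool[elig], function(p) p$id, integer(1))
      elig <- elig[order(last_end, ids)]
      for (i in elig) {
        if (nrow(assignments) >= cohort_size) break
        ok <- allowed_doses(pool[[i]], next_dose, scheme, n_doses, eliminated)
        if (length(ok) == 1) {
          z <- if (ok < max(pool[[i]]$history$dose)) 2L else 1L
          assignments <- take("retreat", i, ok, z)
        }
      }
    }
  }
  # (3) new enrollments
  while (nrow(assignments) < cohort_size) {
    assignments <- take("new", NA_integer_, next_dose, 1L)
  }
  assignments
}

#' Export a patient pool as a long-format ledger
#'
#' @param pool list of [patient_record]s.
#' @return data.frame with one row per treatment cycle.
#' @export
patient_ledger <- function(pool) {
  if (length(pool) == 0) {
    return(data.frame(id = integer(), arrival_week = numeric(),
                      cycle = integer(), dose = integer(),
                      start_week = numeric(), end_week = numeric(),
                      outcome = integer(), z = integer()))
  }
  do.call(rbind, lapply(pool, function(p) {
    if (nrow(p$history) == 0) return(NULL)
    data.frame(id = p$id, arrival_week = p$arrival_week,
               cycle = seq_len(nrow(p$history)), p$history)
  }))
}
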