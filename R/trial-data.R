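#' Patient-by-dose trial data
#'
#' Container for the observed data of an intra-patient dose-escalation trial:
#' a binary DLT outcome matrix `y` (patients in rows, dose levels in columns),
#' an indicator matrix `treated` marking which cells were actually observed,
#' and an assignment-type matrix `assign_type` distinguishing newly
#' enrolled / up-retreated observations (1) from down-retreated observations
#' (2, flexible-allocation schemes only). Untreated cells of `y` and
#' `assign_type` are ignored.
#'
#' A patient may be treated at up to three distinct dose levels, and at most
#' once at any given dose level, so the per-dose totals `n_k` sum to at least
#' the number of patients.
#'
#' @param y integer/numeric matrix (n x K) of 0/1 DLT outcomes; values in
#'   untreated cells are ignored (may be NA).
#' @param treated binary matrix (n x K); 1 where an observation exists.
#' @param assign_type matrix (n x K) with entries 1 or 2 where treated;
#'   defaults to all 1 (no down-retreats).
#' @param max_cycles maximum distinct dose levels per patient (default 3).
#' @return An object of class `trial_data` with elements `y`, `treated`,
#'   `assign_type`, `n_patients`, `n_doses`.
#' @examples
#' d <- trial_data(y = matrix(c(0, 1), 1, 2), treated = matrix(c(1, 1), 1, 2))
#' dose_totals(d)
#' @export
trial_data <- function(y, treated, assign_type = NULL, max_cycles = 3L) {
  y <- as.matrix(y)
  treated <- as.matrix(treated)
  stopifnot(all(dim(y) == dim(treated)))
  if (is.null(assign_type)) {
    assign_type <- matrix(1L, nrow(y), ncol(y))
  }
  assign_type <- as.matrix(assign_type)
  stopifnot(all(dim(assign_type) == dim(y)))
  storage.mode(treated) <- "integer"
  storage.mode(assign_type) <- "integer"
  if (!all(treated %in% c(0L, 1L))) {
    stop("'treated' must be a 0/1 matrix")
  }
  obs <- treated == 1L
  if (any(obs) && !all(y[obs] %in% c(0, 1))) {
    stop("observed outcomes must be 0 or 1")
  }
  if (any(obs) && !all(assign_type[obs] %in% c(1L, 2L))) {
    stop("assignment types must be 1 (new/up-retreat) or 2 (down-retreat)")
  }
  if (nrow(y) > 0 && any(rowSums(treated) > max_cycles)) {
    stop("a patient may be treated at no more than ", max_cycles,
         " dose levels")
  }
  y[!obs] <- NA_real_
  structure(
    list(y = y, treated = treated, assign_type = assign_type,
         n_patients = nrow(y), n_doses = ncol(y)),
    class = "trial_data"
  )
}

#' @export
print.trial_data <- function(x, ...) {
  tot <- dose_totals(x)
  cat("trial_data:", x$n_patients, "patients x", x$n_doses, "dose levels;",
      sum(x$treated), "observations\n")
  cat("  DLTs/treated per dose:",
      paste(sprintf("%d/%d", tot$y_k, tot$n_k), collapse = " "), "\n")
  invisible(x)
}

#' Per-dose DLT and treatment totals
#'
#' @param data a [trial_data] object.
#' @return list with integer vectors `y_k` (DLT counts) and `n_k`
#'   (observations) per dose level.
#' @export
dose_totals <- function(data) {
  stopifnot(inherits(data, "trial_data"))
  if (data$n_patients == 0) {
    return(list(y_k = integer(data$n_doses), n_k = integer(data$n_doses)))
  }
  yy <- data$y
  yy[data$treated == 0L] <- 0
  list(y_k = as.integer(colSums(yy)),
       n_k = as.integer(colSums(data$treated)))
}

#' Empty trial data
#'
#' @param n_doses number of dose levels K.
#' @param n_patients number of (untreated) patients, default 0.
#' @return a [trial_data] object with no observations.
#' @export
empty_trial_data <- function(n_doses, n_patients = 0L) {
  trial_data(y = matrix(NA_real_, n_patients, n_doses),
             treated = matrix(0L, n_patients, n_doses))
}

#' Convert trial data to/from long format
#'
#' The long format has one row per observation with columns `patient_id`,
#' `dose_level` (1-based), `outcome`, `assign_type` and `cycle_index`
#' (the rank of the dose in the patient's treatment order; for matrix data
#' the within-patient order of the treated doses is used).
#'
#' @param data a [trial_data] object.
#' @return data.frame in long format.
#' @export
as_long_format <- function(data) {
  stopifnot(inherits(data, "trial_data"))
  rows <- which(data$treated == 1L, arr.ind = TRUE)
  if (nrow(rows) == 0) {
    return(data.frame(patient_id = integer(), dose_level = integer(),
                      outcome = integer(), assign_type = integer(),
                      cycle_index = integer()))
  }
  ord <- order(rows[, 1], rows[, 2])
  rows <- rows[ord, , drop = FALSE]
  cyc <- stats::ave(rows[, 2], rows[, 1], FUN = seq_along)
  data.frame(
    patient_id = as.integer(rows[, 1]),
    dose_level = as.integer(rows[, 2]),
    outcome = as.integer(data$y[rows]),
    assign_type = as.integer(data$assign_type[rows]),
    cycle_index = as.integer(cyc)
  )
}

#' @rdname as_long_format
#' @param df long-format data.frame with at least `patient_id`, `dose_level`,
#'   `outcome`; optional `assign_type` (default 1).
#' @param n_doses number of dose levels; defaults to `max(dose_level)`.
#' @export
from_long_format <- function(df, n_doses = NULL) {
  stopifnot(all(c("patient_id", "dose_level", "outcome") %in% names(df)))
  if (is.null(n_doses)) n_doses <- max(df$dose_level)
  ids <- sort(unique(df$patient_id))
  n <- length(ids)
  y <- matrix(NA_real_, n, n_doses)
  tr <- matrix(0L, n, n_doses)
  at <- matrix(1L, n, n_doses)
  zt <- if ("assign_type" %in% names(df)) df$assign_type else rep(1L, nrow(df))
  for (r in seq_len(nrow(df))) {
    i <- match(df$patient_id[r], ids)
    k <- df$dose_level[r]
    if (tr[i, k] == 1L) {
      stop("duplicate observation for patient ", df$patient_id[r],
           " at dose ", k)
    }
    tr[i, k] <- 1L
    y[i, k] <- df$outcome[r]
    at[i, k] <- as.integer(zt[r])
  }
  trial_data(y, tr, at)
}

#' Read/write trial data as CSV
#'
#' @param file path to a CSV file in the long format of [as_long_format()].
#' @param n_doses optional dose count override.
#' @return [trial_data] for `read_trial_data`; invisible `file` path for
#'   `write_trial_data`.
#' @export
read_trial_data <- function(file, n_doses = NULL) {
  from_long_format(utils::read.csv(file), n_doses = n_doses)
}

#' @rdname read_trial_data
#' @param data a [trial_data] object.
#' @export
write_trial_data <- function(data, file) {
  utils::write.csv(as_long_format(data), file, row.names = FALSE)
  invisible(file)
}
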