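#' Toxicity scenario
#'
#' True per-dose DLT probabilities with the target rate and (when a dose's
#' probability equals the target) the true MTD index.
#'
#' @param probs non-decreasing vector of true DLT probabilities.
#' @param phi target DLT rate.
#' @param mtd_index true MTD index, or NA when no dose attains the target.
#' @param label optional label.
#' @return object of class `scenario`.
#' @export
scenario <- function(probs, phi, mtd_index = NA_integer_, label = "") {
  stopifnot(all(diff(probs) >= 0), all(probs >= 0 & probs <= 1),
            phi > 0, phi < 1)
  if (!is.na(mtd_index)) {
    stopifnot(mtd_index >= 1, mtd_index <= length(probs))
  }
  structure(list(probs = probs, phi = phi,
                 mtd_index = as.integer(mtd_index), label = label),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("scenario", x$label, ": phi =", x$phi, "\n  p =",
      paste(format(x$probs, nsmall = 2), collapse = " "),
      "\n  MTD =", ifelse(is.na(x$mtd_index), "none", x$mtd_index), "\n")
  invisible(x)
}

#' Fixed simulation scenario sets
#'
#' The two benchmark sets of fixed dose-toxicity scenarios: set A has six
#' five-dose scenarios with target rate 0.33 (the MTD probability equals
#' 0.33 except in scenario 6, where every dose is above the target); set B
#' has eight seven-dose scenarios with target rate 0.20 (no dose attains the
#' target in scenario 4).
#'
#' @param set_id `"A"` or `"B"`.
#' @return list of [scenario] objects.
#' @examples
#' fixed_scenarios("A")[[1]]
#' @export
fixed_scenarios <- function(set_id = c("A", "B")) {
  set_id <- match.arg(set_id)
  if (set_id == "A") {
    tab <- list(
      c(0.33, 0.45, 0.58, 0.70, 0.80),
      c(0.18, 0.33, 0.52, 0.60, 0.70),
      c(0.12, 0.22, 0.33, 0.40, 0.50),
      c(0.01, 0.02, 0.03, 0.33, 0.50),
      c(0.00, 0.00, 0.05, 0.10, 0.33),
      c(0.45, 0.55, 0.65, 0.75, 0.85)
    )
    phi <- 0.33
  } else {
    tab <- list(
      c(0.05, 0.20, 0.46, 0.50, 0.60, 0.70, 0.80),
      c(0.02, 0.05, 0.20, 0.28, 0.34, 0.40, 0.44),
      c(0.01, 0.05, 0.10, 0.20, 0.32, 0.50, 0.70),
      c(0.01, 0.04, 0.07, 0.10, 0.50, 0.70, 0.90),
      c(0.01, 0.05, 0.10, 0.14, 0.20, 0.26, 0.34),
      c(0.01, 0.02, 0.03, 0.05, 0.20, 0.40, 0.50),
      c(0.01, 0.04, 0.07, 0.10, 0.15, 0.20, 0.25),
      c(0.01, 0.02, 0.03, 0.04, 0.05, 0.20, 0.45)
    )
    phi <- 0.20
  }
  lapply(seq_along(tab), function(s) {
    p <- tab[[s]]
    mtd <- which(abs(p - phi) < 1e-9)
    scenario(p, phi,
             mtd_index = if (length(mtd) == 1) mtd else NA_integer_,
             label = paste0(set_id, s))
  })
}

# Inverse-CDF sampler from the exponentially tilted uniform density
# f(x) propto exp(lambda * x) on (0, room); lambda is solved (and cached)
# so that the mean equals m (uniform when m = room/2).
.tilt_cache <- new.env(parent = emptyenv())
r_tilted_gap <- function(m, room) {
  stopifnot(m > 0, m < room)
  if (abs(m - room / 2) < 1e-9 * room) return(stats::runif(1, 0, room))
  key <- paste(m, room, sep = "|")
  lam <- .tilt_cache[[key]]
  if (is.null(lam)) {
    mean_fn <- function(l) {
      # mean of tilted uniform on (0, room)
      room / (1 - exp(-l * room)) - 1 / l
    }
    lam <- stats::uniroot(function(l) mean_fn(l) - m,
                          lower = -500 / room, upper = 500 / room,
                          tol = 1e-10)$root
    .tilt_cache[[key]] <- lam
  }
  u <- stats::runif(1)
  log1p(u * (exp(lam * room) - 1)) / lam
}

#' Random dose-toxicity scenario generator
#'
#' Generates monotone scenarios indexed by the average probability
#' difference around the target (APDT). The MTD position is drawn uniformly
#' over the dose levels and its probability set to `phi`; each adjacent
#' neighbor's probability differs from `phi` by a random gap whose expected
#' value equals `apdt` exactly (a tilted-uniform gap bounded by the room to
#' the probability boundary); gaps beyond the immediate neighbors are
#' exponential with mean `apdt`, clipped so probabilities stay within
#' (0.001, 0.999).
#'
#' @param n_doses number of dose levels K (>= 2).
#' @param phi target DLT rate.
#' @param apdt average probability difference around the target, in
#'   (0, min(phi, 1 - phi) - 0.001).
#' @return a [scenario] with `mtd_index` set.
#' @export
random_scenario <- function(n_doses, phi, apdt) {
  stopifnot(n_doses >= 2, apdt > 0, apdt < 0.5)
  lo <- 0.001
  hi <- 0.999
  if (apdt >= phi - lo || apdt >= hi - phi) {
    stop("infeasible apdt for this target rate")
  }
  m <- sample.int(n_doses, 1)
  p <- numeric(n_doses)
  p[m] <- phi
  if (m < n_doses) p[m + 1] <- phi + r_tilted_gap(apdt, hi - phi)
  if (m > 1) p[m - 1] <- phi - r_tilted_gap(apdt, phi - lo)
  if (m + 2 <= n_doses) {
    for (k in (m + 2):n_doses) {
      p[k] <- min(p[k - 1] + stats::rexp(1, 1 / apdt), hi)
    }
  }
  if (m - 2 >= 1) {
    for (k in (m - 2):1) {
      p[k] <- max(p[k + 1] - stats::rexp(1, 1 / apdt), lo)
    }
  }
  scenario(p, phi, mtd_index = m,
           label = sprintf("random(apdt=%.2f)", apdt))
}

#' Serialize a scenario list
#' @param scenarios list of [scenario] objects.
#' @return data.frame with one row per scenario.
#' @export
scenarios_to_df <- function(scenarios) {
  do.call(rbind, lapply(scenarios, function(s) {
    data.frame(label = s$label, phi = s$phi, mtd_index = s$mtd_index,
               t(stats::setNames(s$probs,
                                 paste0("p", seq_along(s$probs)))))
  }))
}
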