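# Grouped five-year survival and the Kaplan-Meier product-limit estimator.

.survival_bin_labels <- c("1-12", "13-24", "25-36", "37-48", "49-60", ">60")

#' Grouped survival lengths
#'
#' Six ordered bins of survival length in months — 1-12, 13-24, 25-36,
#' 37-48, 49-60 and beyond 60 — with nonnegative counts summing to the
#' cohort size. Only the final bin holds five-year survivors.
#'
#' @param counts Numeric vector of six nonnegative counts, in bin order.
#' @return A `survrule_grouped` object (named integer vector).
#' @export
grouped_lengths <- function(counts) {
  if (length(counts) != length(.survival_bin_labels)) {
    stop("expected ", length(.survival_bin_labels), " bin counts")
  }
  if (anyNA(counts) || any(counts < 0)) stop("counts must be nonnegative")
  if (sum(counts) < 1) stop("empty cohort: counts sum to zero")
  structure(stats::setNames(as.integer(counts), .survival_bin_labels),
            class = "survrule_grouped")
}

#' Bin a cohort's survival months into grouped lengths
#'
#' @param cohort A `survrule_cohort` or an integer vector of survival
#'   months.
#' @return A `survrule_grouped`.
#' @export
bin_survival_lengths <- function(cohort) {
  months <- if (is.data.frame(cohort)) cohort$survival_months else cohort
  months <- as.integer(months)
  if (anyNA(months) || any(months < 1L)) {
    stop("survival months must be positive integers")
  }
  idx <- findInterval(months, c(1, 13, 25, 37, 49, 61))
  grouped_lengths(tabulate(idx, nbins = 6L))
}

#' Grouped five-year survival rate
#'
#' The plain proportion of patients in the beyond-60-months bin — the
#' five-year overall survival rate of a cohort with complete follow-up.
#'
#' @param g A `survrule_grouped`.
#' @return A single proportion.
#' @export
grouped_survival_rate <- function(g) {
  stopifnot(inherits(g, "survrule_grouped"))
  unname(g[length(g)] / sum(g))
}

#' Kaplan-Meier product-limit estimate
#'
#' S(t) = prod over distinct event times t_i <= t of (1 - d_i / n_i), where
#' d_i events occur among n_i subjects at risk just before t_i. Censored
#' observations leave the risk set after their time (at ties, events
#' precede censorings, the standard convention).
#'
#' @param times Positive observation times (months).
#' @param events Logical (or 0/1) event indicators; `FALSE` = censored.
#' @return A `survrule_km` data.frame with one row per distinct observed
#'   time: `time`, `n_risk`, `n_event`, `n_censor`, `survival`
#'   (right-continuous step value at that time).
#' @export
km_estimate <- function(times, events) {
  times <- as.numeric(times)
  events <- as.logical(events)
  if (length(times) != length(events)) {
    stop("'times' and 'events' must have equal length")
  }
  if (length(times) == 0L) stop("no observations")
  if (anyNA(times) || any(times <= 0)) stop("times must be positive")
  if (anyNA(events)) stop("'events' must not contain NA")
  o <- order(times)
  times <- times[o]; events <- events[o]
  ut <- unique(times)
  n_event <- vapply(ut, function(t) sum(events[times == t]), 0L)
  n_censor <- vapply(ut, function(t) sum(!events[times == t]), 0L)
  # at risk just before each distinct time
  n_at <- length(times) - c(0L, cumsum(n_event + n_censor))[seq_along(ut)]
  surv <- cumprod(1 - n_event / n_at)
  structure(
    data.frame(time = ut, n_risk = as.integer(n_at),
               n_event = as.integer(n_event),
               n_censor = as.integer(n_censor), survival = surv),
    class = c("survrule_km", "data.frame"))
}

#' Evaluate a survival curve at a time point
#'
#' Right-continuous step evaluation: S(t) is the estimate at the last
#' observed time at or before `t`; before the first observed time S(t) = 1.
#'
#' @param curve A `survrule_km`.
#' @param t Time (months), >= 0. Vectorised.
#' @return Survival probabilities.
#' @export
survival_rate_at <- function(curve, t) {
  stopifnot(inherits(curve, "survrule_km"))
  if (any(t < 0)) stop("'t' must be nonnegative")
  idx <- findInterval(t, curve$time)
  ifelse(idx == 0L, 1, curve$survival[pmax(idx, 1L)])
}

#' Write a survival curve as CSV
#'
#' Columns: `time`, `at_risk`, `events`, `survival`.
#'
#' @param curve A `survrule_km`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_km_csv <- function(curve, path) {
  utils::write.csv(
    data.frame(time = curve$time, at_risk = curve$n_risk,
               events = curve$n_event, survival = curve$survival),
    path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
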