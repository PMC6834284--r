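#' Kaplan-Meier product-limit estimate
#'
#' Standard product-limit estimator under right-censoring.  Censored
#' observations tied with deaths at a time `t` are counted as at risk at
#' `t` (the usual convention).
#'
#' @param times survival times in days (nonnegative).
#' @param events event indicators (1 = death, 0 = censored).
#' @return A `km_curve` list: `event_times` (distinct death times,
#'   increasing), `survival` (S after each death time), `at_risk` (number
#'   at risk just before each death time), `n_events` (deaths at each),
#'   and `n` (group size).
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0L) stop("empty group")
  stopifnot(length(times) == length(events), all(times >= 0),
            all(events %in% c(0, 1)))
  dt <- sort(unique(times[events == 1]))
  at_risk <- vapply(dt, function(t) sum(times >= t), numeric(1))
  n_events <- vapply(dt, function(t) sum(times == t & events == 1),
                     numeric(1))
  surv <- cumprod(1 - n_events / at_risk)
  structure(list(event_times = dt, survival = surv, at_risk = at_risk,
                 n_events = n_events, n = length(times)),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Step-function evaluation: S = 1 before the first death, the last
#' estimated value is carried forward beyond follow-up.
#'
#' @param curve a [km_estimate()] result.
#' @param t times (days) at which to evaluate.
#' @return survival probabilities at `t`.
#' @export
km_survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  idx <- findInterval(t, curve$event_times)
  ifelse(idx == 0, 1, curve$survival[pmax(idx, 1)])
}

#' Two-group logrank test
#'
#' At each distinct death time j (pooled over both groups) with `d_j`
#' deaths, `n_j` at risk overall and `n_1j` at risk in the low group, the
#' low group's expected deaths are `E_1j = d_j n_1j / n_j` and the
#' hypergeometric variance is
#' `V_j = n_1j n_2j d_j (n_j - d_j) / (n_j^2 (n_j - 1))`.
#' The statistic `(sum O_1j - sum E_1j)^2 / sum V_j` is referred to the
#' upper tail of a chi-square with one degree of freedom.
#'
#' @param times_low,events_low low-group survival times and indicators.
#' @param times_high,events_high high-group survival times and indicators.
#' @return A `logrank_result` list: `chi_square`, `p_value`,
#'   `observed_low`, `expected_low`, `observed_high`, `expected_high`,
#'   `variance_sum`, `degenerate` (TRUE when the variance sum is zero, in
#'   which case p = 1).
#' @export
logrank <- function(times_low, events_low, times_high, events_high) {
  if (length(times_low) == 0L || length(times_high) == 0L)
    stop("both groups must be nonempty")
  times <- c(times_low, times_high)
  events <- c(events_low, events_high)
  if (sum(events) == 0L) stop("no deaths in either group")
  in_low <- rep(c(TRUE, FALSE), c(length(times_low), length(times_high)))
  dt <- sort(unique(times[events == 1]))
  O1 <- E1 <- V <- 0
  O_total <- 0
  for (t in dt) {
    n_j <- sum(times >= t)
    n1_j <- sum(times >= t & in_low)
    d_j <- sum(times == t & events == 1)
    d1_j <- sum(times == t & events == 1 & in_low)
    O1 <- O1 + d1_j
    O_total <- O_total + d_j
    E1 <- E1 + d_j * n1_j / n_j
    if (n_j > 1)
      V <- V + n1_j * (n_j - n1_j) * d_j * (n_j - d_j) / (n_j^2 * (n_j - 1))
  }
  degenerate <- V <= 1e-12
  if (degenerate) {
    chi <- 0
    p <- 1
  } else {
    chi <- (O1 - E1)^2 / V
    p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  }
  structure(list(chi_square = chi, p_value = p,
                 observed_low = O1, expected_low = E1,
                 observed_high = O_total - O1,
                 expected_high = O_total - E1,
                 variance_sum = V, degenerate = degenerate),
            class = "logrank_result")
}

#' Group effect sizes: O/E hazard ratio and mortality at fixed horizons
#'
#' The hazard ratio is the observed/expected ratio estimator
#' `(O_high / E_high) / (O_low / E_low)` from the logrank tallies — not a
#' proportional-hazards model fit.  When either group has zero observed
#' deaths, 0.5 is added to all four tallies (continuity correction,
#' flagged in the result).  Mortality per group at each horizon is
#' `1 - S_KM(horizon)`, with the last Kaplan-Meier value carried forward
#' beyond follow-up.
#'
#' @param times_low,events_low low-group data.
#' @param times_high,events_high high-group data.
#' @param horizons days at which mortality is reported (default 1, 2 and
#'   5 years as 365, 730, 1825 days).
#' @return A `group_effect` list: `hazard_ratio`, `corrected` (continuity
#'   correction applied), `mortality_low`, `mortality_high` (named by
#'   horizon).
#' @export
group_effect <- function(times_low, events_low, times_high, events_high,
                         horizons = c(365, 730, 1825)) {
  if (any(horizons <= 0)) stop("horizons must be positive")
  lr <- logrank(times_low, events_low, times_high, events_high)
  OL <- lr$observed_low; EL <- lr$expected_low
  OH <- lr$observed_high; EH <- lr$expected_high
  corrected <- (OL == 0 || OH == 0)
  if (corrected) {
    OL <- OL + 0.5; EL <- EL + 0.5
    OH <- OH + 0.5; EH <- EH + 0.5
  }
  hr <- (OH / EH) / (OL / EL)
  km_l <- km_estimate(times_low, events_low)
  km_h <- km_estimate(times_high, events_high)
  ml <- 1 - km_survival_at(km_l, horizons)
  mh <- 1 - km_survival_at(km_h, horizons)
  names(ml) <- names(mh) <- paste0(horizons, "d")
  structure(list(hazard_ratio = hr, corrected = corrected,
                 mortality_low = ml, mortality_high = mh),
            class = "group_effect")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: n =", x$n, ",", length(x$event_times),
      "distinct death times\n")
  invisible(x)
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Logrank test: chi-square = %.4g (1 df), p = %.4g\n",
              x$chi_square, x$p_value))
  cat(sprintf("  low:  O = %g, E = %.3f\n", x$observed_low, x$expected_low))
  cat(sprintf("  high: O = %g, E = %.3f\n", x$observed_high,
              x$expected_high))
  invisible(x)
}

# km_estimate on an all-censored group: no death times, survival stays 1.
# km_survival_at handles the empty-event_times case through findInterval
# (idx = 0 everywhere -> 1).
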