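# Kaplan-Meier product-limit estimation and the two-group log-rank test,
# implemented from the definitions (right-censoring throughout).

#' Kaplan-Meier product-limit estimator
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct event times
#' `t_i`, with `d_i` events among `n_i` at risk; censored observations
#' leave the risk set without contributing an event factor.
#'
#' @param times Follow-up times (>= 0).
#' @param events Event indicators, 1 = event, 0 = censored.
#' @return A `km_fit` tibble: one row per distinct observed time with
#'   `time`, `n_risk`, `n_event`, `n_censor`, `surv` (the estimate just
#'   after `time`).
#' @export
km_estimate <- function(times, events) {
  if (any(times < 0, na.rm = TRUE)) abort("Survival times must be >= 0.")
  if (!all(events %in% c(0, 1))) abort("`events` must be 0/1.")
  ok <- complete.cases(times, events)
  times <- times[ok]
  events <- events[ok]
  tt <- sort(unique(times))
  n <- length(times)
  surv <- 1
  rows <- purrr::map(tt, function(t) {
    n_risk <- sum(times >= t)
    d <- sum(times == t & events == 1)
    c_ <- sum(times == t & events == 0)
    if (d > 0) surv <<- surv * (1 - d / n_risk)
    tibble(time = t, n_risk = n_risk, n_event = d, n_censor = c_, surv = surv)
  })
  out <- bind_rows(rows)
  class(out) <- c("km_fit", class(out))
  out
}

#' Evaluate a Kaplan-Meier fit at given times
#'
#' @param fit A `km_fit` from [km_estimate()].
#' @param t Times at which to evaluate the step function.
#' @return Survival probabilities `S(t)` (1 before the first event).
#' @export
km_survival_at <- function(fit, t) {
  vapply(t, function(tt) {
    prior <- fit$surv[fit$time <= tt]
    if (length(prior) == 0L) 1 else prior[length(prior)]
  }, 0)
}

#' Two-group log-rank test
#'
#' At each distinct pooled event time, the observed number of group-1
#' events is compared with its expectation under the pooled risk set
#' (hypergeometric mean `d_j n_{1j} / n_j`, variance
#' `d_j (n_{1j}/n_j)(1 - n_{1j}/n_j)(n_j - d_j)/(n_j - 1)`);
#' `chi^2 = (sum O - sum E)^2 / sum V`, p from chi-square with 1 df.
#' Symmetric in the group labels.
#'
#' @param time1,event1 Follow-up times and 0/1 event flags, group 1.
#' @param time2,event2 Same for group 2.
#' @return List `chisq`, `p`, `observed`, `expected` (group-1 totals).
#' @export
logrank_test <- function(time1, event1, time2, event2) {
  if (any(c(time1, time2) < 0, na.rm = TRUE)) abort("Survival times must be >= 0.")
  times <- c(time1, time2)
  events <- c(event1, event2)
  grp <- rep(1:2, c(length(time1), length(time2)))
  ok <- complete.cases(times, events)
  times <- times[ok]; events <- events[ok]; grp <- grp[ok]
  if (sum(events == 1) == 0L) abort("No events in either group; log-rank undefined.")

  event_times <- sort(unique(times[events == 1]))
  O <- E <- V <- 0
  for (t in event_times) {
    at_risk <- times >= t
    n_j <- sum(at_risk)
    n1_j <- sum(at_risk & grp == 1)
    d_j <- sum(times == t & events == 1)
    d1_j <- sum(times == t & events == 1 & grp == 1)
    O <- O + d1_j
    E <- E + d_j * n1_j / n_j
    if (n_j > 1) {
      V <- V + d_j * (n1_j / n_j) * (1 - n1_j / n_j) * (n_j - d_j) / (n_j - 1)
    }
  }
  if (V == 0) return(list(chisq = 0, p = 1, observed = O, expected = E))
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE),
       observed = O, expected = E)
}

#' Administrative censoring at a fixed horizon
#'
#' Truncates follow-up at `horizon`: observations beyond it are censored at
#' the horizon. Used for early-treatment-window survival contrasts (e.g. a
#' log-rank restricted to the first 18 months).
#'
#' @param times Follow-up times.
#' @param events 0/1 event flags.
#' @param horizon Truncation time (same units as `times`).
#' @return List `times`, `events` after truncation.
#' @export
administrative_censor <- function(times, events, horizon) {
  assert_scalar_number(horizon, "horizon", lower = 0)
  over <- !is.na(times) & times > horizon
  events[over] <- 0
  times[over] <- horizon
  list(times = times, events = events)
}

#' Survival stratification by the median of a marker
#'
#' Median-splits a per-sample marker (e.g. an adaptive epigenetic age) into
#' High/Low groups and runs the two-group log-rank test on overall
#' survival, optionally after administrative censoring at a horizon.
#'
#' @param clinical Clinical tibble with `sample_id`, `os_months`,
#'   `os_event`.
#' @param marker Named numeric vector, sample_id -> marker value.
#' @param horizon_months Optional administrative-censoring horizon.
#' @return List `group` (tibble sample_id/group), `logrank` (list from
#'   [logrank_test()]), `km` (named list of `km_fit` per group).
#' @export
survival_by_median <- function(clinical, marker, horizon_months = NULL) {
  validate_clinical(clinical)
  if (!all(c("os_months", "os_event") %in% names(clinical))) {
    abort("Clinical table needs `os_months` and `os_event`.")
  }
  df <- clinical %>%
    mutate(marker = unname(marker[.data$sample_id])) %>%
    filter(complete.cases(.data$marker, .data$os_months, .data$os_event))
  df$group <- median_stratify(df$marker)
  tt <- df$os_months
  ee <- df$os_event
  if (!is.null(horizon_months)) {
    ac <- administrative_censor(tt, ee, horizon_months)
    tt <- ac$times; ee <- ac$events
  }
  hi <- df$group == "High"
  list(
    group = select(df, "sample_id", "group"),
    logrank = logrank_test(tt[hi], ee[hi], tt[!hi], ee[!hi]),
    km = list(High = km_estimate(tt[hi], ee[hi]),
              Low = km_estimate(tt[!hi], ee[!hi]))
  )
}
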