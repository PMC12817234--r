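# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Kaplan-Meier fit
#' @param x A `km_fit` from [km_estimate()].
#' @param ... Unused.
#' @return Tibble with one row per distinct time (`time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`).
#' @export
tidy.km_fit <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of a Kaplan-Meier fit
#' @param x A `km_fit`.
#' @param ... Unused.
#' @return Tibble `n`, `n_events`, `median_survival` (first time the
#'   estimate drops to <= 0.5; `NA` if it never does).
#' @export
glance.km_fit <- function(x, ...) {
  below <- x$time[x$surv <= 0.5]
  tibble(
    n = if (nrow(x)) x$n_risk[1L] else 0L,
    n_events = sum(x$n_event),
    median_survival = if (length(below)) below[1L] else NA_real_
  )
}

#' Tidy a differential-methylation result
#' @param x A `dmc_result` from [moderated_t_test()].
#' @param ... Unused.
#' @return The per-probe tibble sorted by p-value.
#' @export
tidy.dmc_result <- function(x, ...) {
  out <- tibble::as_tibble(unclass(x))
  dplyr::arrange(out, .data$p)
}

#' One-row summary of a differential-methylation result
#' @param x A `dmc_result`.
#' @param ... Unused.
#' @return Tibble `n_probes`, `n_dmc`, `prior_df`, `prior_var`.
#' @export
glance.dmc_result <- function(x, ...) {
  mod <- attr(x, "moderation")
  tibble(
    n_probes = nrow(x),
    n_dmc = sum(x$is_dmc, na.rm = TRUE),
    prior_df = mod$d0,
    prior_var = mod$s0_sq
  )
}
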