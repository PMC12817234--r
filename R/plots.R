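# ggplot2 views of the main result types.

#' Plot Kaplan-Meier curves
#'
#' @param object A `km_fit`, or a named list of them (one curve per group).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.km_fit <- function(object, ...) {
  df <- tidy(object)
  df <- dplyr::bind_rows(tibble(time = 0, surv = 1), df[, c("time", "surv")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves for several groups
#'
#' @param fits Named list of `km_fit` objects.
#' @return A ggplot with one step curve per group.
#' @export
plot_km_groups <- function(fits) {
  df <- purrr::imap(fits, function(f, g) {
    d <- tidy(f)[, c("time", "surv")]
    dplyr::bind_rows(tibble(time = 0, surv = 1), d) %>%
      dplyr::mutate(group = g)
  }) %>% dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$surv, colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Epigenetic age against chronological age
#'
#' Scatter with the y = x identity line; vertical distance from the line is
#' the age acceleration.
#'
#' @param eaa Tibble from [compute_eaa()].
#' @return A ggplot, faceted by clock when several are present.
#' @export
plot_ea_vs_age <- function(eaa) {
  p <- ggplot2::ggplot(eaa, ggplot2::aes(.data$chronological_age,
                                         .data$epigenetic_age)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Chronological age (years)",
                  y = "Epigenetic age (years)") +
    ggplot2::theme_minimal()
  if (length(unique(eaa$clock)) > 1L) {
    p <- p + ggplot2::facet_wrap(~clock, scales = "free_y")
  }
  p
}

#' Volcano view of a differential-methylation result
#'
#' @param object A `dmc_result`.
#' @param ... Unused.
#' @return A ggplot of mean M-value difference vs -log10 FDR.
#' @export
autoplot.dmc_result <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(.data$mean_diff, -log10(.data$fdr),
                                   colour = .data$is_dmc)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Mean difference (M-units)",
                  y = expression(-log[10] ~ FDR), colour = "DMC") +
    ggplot2::theme_minimal()
}

#' TF enrichment bar chart
#'
#' @param enrichment Tibble from [tf_enrichment()].
#' @param top Number of TFs shown (default 15).
#' @return A ggplot of -log10 FDR per TF.
#' @export
plot_enrichment <- function(enrichment, top = 15L) {
  df <- enrichment %>%
    dplyr::filter(!.data$excluded) %>%
    dplyr::slice_head(n = top) %>%
    dplyr::mutate(tf = factor(.data$tf, levels = rev(.data$tf)))
  ggplot2::ggplot(df, ggplot2::aes(-log10(.data$fdr), .data$tf,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = expression(-log[10] ~ FDR), y = NULL,
                  fill = "FDR < threshold") +
    ggplot2::theme_minimal()
}

#' Methylation of low-methylated PRC2 region bins across age groups
#'
#' @param strata Tibble from [lmc_stratification()].
#' @return A ggplot: one line per region bin over the sample groups.
#' @export
plot_lmc_strata <- function(strata) {
  ggplot2::ggplot(strata, ggplot2::aes(.data$group, .data$mean_beta,
                                       colour = factor(.data$region_bin),
                                       group = .data$region_bin)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Sample group (young to old)", y = "Mean beta",
                  colour = "Region bin") +
    ggplot2::theme_minimal()
}
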