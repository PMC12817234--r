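# Hypergeometric enrichment of TF-binding-region CpGs among DMCs, and
# age-adjusted correlation of epigenetic age with TF-site methylation.

#' Hypergeometric TF enrichment of DMCs
#'
#' For each transcription factor: the universe of `N` analyzed CpGs contains
#' `K` CpGs inside the TF's binding regions; among `n` DMCs, `k` fall inside
#' them. The enrichment p-value is the upper tail `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`. TFs whose binding regions overlap fewer
#' than `min_overlap_cpgs` universe CpGs are flagged excluded (a guard
#' against tiny annotation sets) and omitted from the BH family; setting
#' `exclude_on = "dmc_overlap"` applies the same floor to `k` instead.
#'
#' @param dmc Character vector of DMC probe IDs (subset of `universe`).
#' @param tf_probe_sets Named list, TF -> character vector of probe IDs
#'   inside that TF's binding regions.
#' @param universe Character vector of all analyzed probe IDs.
#' @param min_overlap_cpgs Exclusion floor (default 5).
#' @param fdr_threshold Significance threshold on BH-adjusted p (default
#'   0.05).
#' @param exclude_on `"universe_overlap"` (default; floor applies to `K`) or
#'   `"dmc_overlap"` (floor applies to `k`).
#' @return Tibble `tf`, `k`, `K`, `n`, `N`, `p`, `fdr`, `excluded`,
#'   `exclude_reason`, `significant`, sorted by `fdr` with excluded TFs
#'   last.
#' @export
tf_enrichment <- function(dmc, tf_probe_sets, universe,
                          min_overlap_cpgs = 5L, fdr_threshold = 0.05,
                          exclude_on = c("universe_overlap", "dmc_overlap")) {
  exclude_on <- match.arg(exclude_on)
  min_overlap_cpgs <- assert_count(min_overlap_cpgs, "min_overlap_cpgs", 1L)
  universe <- unique(universe)
  dmc <- unique(dmc)
  if (length(universe) == 0L) abort("Empty universe.")
  if (length(dmc) == 0L) abort("Empty DMC set.")
  if (!all(dmc %in% universe)) abort("All DMCs must lie in the universe.")
  N <- length(universe)
  n <- length(dmc)

  rows <- purrr::imap(tf_probe_sets, function(probes, tf) {
    set <- intersect(unique(probes), universe)
    K <- length(set)
    k <- length(intersect(set, dmc))
    p <- if (K == 0L) 1 else phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    tibble(tf = tf, k = k, K = K, n = n, N = N, p = p)
  })
  out <- bind_rows(rows)
  out$excluded <- if (exclude_on == "universe_overlap") {
    out$K < min_overlap_cpgs
  } else {
    out$k < min_overlap_cpgs
  }
  out$exclude_reason <- ifelse(
    out$excluded,
    sprintf("fewer than %d overlapping CpGs (%s)", min_overlap_cpgs, exclude_on),
    NA_character_)
  out$fdr <- NA_real_
  tested <- !out$excluded
  out$fdr[tested] <- p.adjust(out$p[tested], method = "BH")
  out$significant <- !out$excluded & out$fdr < fdr_threshold
  out %>% arrange(.data$excluded, .data$fdr, .data$p, .data$tf)
}

#' Partial Pearson correlation controlling one covariate
#'
#' Correlates the residuals of `x ~ control` and `y ~ control` (simple
#' linear regressions), equal to the closed-form first-order partial
#' correlation
#' `(r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) (1 - r_yz^2))`.
#'
#' @param x,y,control Numeric vectors of equal length (>= 4 complete
#'   observations).
#' @return Scalar partial correlation.
#' @export
partial_pearson <- function(x, y, control) {
  ok <- complete.cases(x, y, control)
  x <- x[ok]; y <- y[ok]; z <- control[ok]
  if (length(x) < 4L) abort("Partial correlation needs >= 4 observations.")
  if (sd(z) == 0) {
    # constant control: nothing to remove
    return(cor(x, y))
  }
  rx <- residuals(lm(x ~ z))
  ry <- residuals(lm(y ~ z))
  if (sd(rx) < 1e-12 * max(sd(x), 1) || sd(ry) < 1e-12 * max(sd(y), 1)) {
    abort("Partial correlation undefined: zero residual variance after controlling.")
  }
  cor(rx, ry)
}

#' Age-adjusted correlation of epigenetic age with TF-site methylation
#'
#' For each TF, computes the partial Pearson correlation between per-sample
#' mean methylation at its binding sites and epigenetic age, controlling
#' chronological age, and ranks TFs by absolute correlation.
#'
#' @param tf_scores Tibble of [region_methylation_score()] rows over TFs
#'   (`sample_id`, `set_name`, `mean_beta`).
#' @param ea Tibble with `sample_id`, `epigenetic_age`.
#' @param clinical Clinical tibble with `sample_id`, `age_years`.
#' @param top_k Rows to flag as the top ranking (default 20).
#' @return Tibble `tf`, `partial_r`, `n`, `rank`, `top` sorted by
#'   `|partial_r|` descending; TFs with constant scores get `NA` and are
#'   excluded from ranking.
#' @export
ea_tf_methylation_correlation <- function(tf_scores, ea, clinical, top_k = 20L) {
  df <- tf_scores %>%
    left_join(select(ea, "sample_id", "epigenetic_age"), by = "sample_id") %>%
    left_join(select(clinical, "sample_id", "age_years"), by = "sample_id")
  out <- df %>%
    group_by(tf = .data$set_name) %>%
    summarise(
      n = sum(complete.cases(.data$mean_beta, .data$epigenetic_age,
                             .data$age_years)),
      partial_r = if (sd(.data$mean_beta, na.rm = TRUE) == 0) NA_real_ else
        partial_pearson(.data$mean_beta, .data$epigenetic_age, .data$age_years),
      .groups = "drop"
    ) %>%
    arrange(desc(abs(.data$partial_r)))
  out$rank <- NA_integer_
  ranked <- which(!is.na(out$partial_r))
  out$rank[ranked] <- seq_along(ranked)
  out$top <- !is.na(out$rank) & out$rank <= top_k
  out
}
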