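# Two-group differential methylation on M-values with empirical-Bayes
# variance moderation. The moderation scheme is the standard scaled-F
# hierarchical model: per-probe sample variances s_g^2 ~ s0^2 * F(d, d0)
# marginally; the prior (d0, s0^2) is estimated by method of moments on
# log-variances, and posterior variances shrink s_g^2 toward s0^2.

#' Invert the trigamma function
#'
#' Solves `trigamma(x) = y` for `x > 0` by Newton iteration on a convex
#' reparameterization; used to estimate the prior degrees of freedom.
#'
#' @param y Positive numeric values.
#' @return `x` with `trigamma(x) = y`; `Inf` where `y <= 0`.
#' @export
trigamma_inverse <- function(y) {
  vapply(y, function(yy) {
    if (!is.finite(yy) || yy <= 0) return(Inf)
    if (yy > 1e7) return(1 / sqrt(yy))
    if (yy < 1e-6) return(1 / yy)
    x <- 0.5 + 1 / yy
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, 2L)
      x <- x + dif
      if (abs(dif) / x < 1e-10) break
    }
    x
  }, 0)
}

#' Estimate variance-moderation prior by method of moments
#'
#' Works on `e_g = log(s_g^2) - digamma(d/2) + log(d/2)`, an unbiased
#' estimate of `log(sigma_g^2)` under the chi-square sampling model:
#' the excess spread of `e` over `trigamma(d/2)` determines the prior
#' degrees of freedom `d0` via `trigamma(d0/2) = var(e) - trigamma(d/2)`
#' (with `d0 = Inf` when there is no excess spread), and
#' `s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`.
#'
#' @param sample_variances Per-probe sample variances (>= 10 probes).
#' @param d Residual degrees of freedom per probe.
#' @return List `d0`, `s0_sq`, `d`.
#' @export
fit_moderation <- function(sample_variances, d) {
  if (length(sample_variances) < 10L) {
    abort("Variance moderation needs >= 10 probes.")
  }
  assert_scalar_number(d, "d", 1)
  s2 <- sample_variances[is.finite(sample_variances)]
  if (all(s2 == 0)) abort("All probe variances are zero; nothing to moderate.")
  s2 <- pmax(s2, 1e-12)
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  excess <- var(e) - trigamma(d / 2)
  if (excess <= 0) {
    d0 <- Inf
    s0_sq <- mean(s2)
  } else {
    d0 <- 2 * trigamma_inverse(max(excess, 1e-8))
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_sq = s0_sq, d = d)
}

#' Moderated two-group t-tests over probes
#'
#' Per probe: group-mean difference on M-values, pooled within-group
#' variance with `d = n1 + n2 - 2` df, posterior (shrunken) variance
#' `s~^2 = (d0*s0^2 + d*s^2) / (d0 + d)`, moderated
#' `t~ = diff / (s~ * sqrt(1/n1 + 1/n2))`, two-sided p from the
#' t-distribution with `d0 + d` df (df capped at 1e6 when the prior
#' dominates), Benjamini-Hochberg adjustment across probes. Probes with
#' missing values use complete-case group means with per-probe df
#' adjustment.
#'
#' @param m M-value matrix (probes x samples).
#' @param groups Two-level factor/character vector along samples; the
#'   difference reported is `first level - second level` (levels in order of
#'   first appearance for character input).
#' @param params Optional moderation prior from [fit_moderation()];
#'   estimated from the data when `NULL`.
#' @param fdr_threshold DMC call threshold on BH-adjusted p (default 0.05).
#' @return Tibble `probe_id`, `n1`, `n2`, `mean_diff`, `pooled_sd`,
#'   `moderated_t`, `df_total`, `p`, `fdr`, `is_dmc`; attribute
#'   `moderation` carries the prior used.
#' @export
moderated_t_test <- function(m, groups, params = NULL, fdr_threshold = 0.05) {
  if (!is.matrix(m)) abort("`m` must be a matrix (probes x samples).")
  assert_fraction(fdr_threshold, "fdr_threshold")
  if (length(groups) != ncol(m)) abort("`groups` must match the sample columns.")
  f <- if (is.factor(groups)) droplevels(groups) else
    factor(groups, levels = unique(groups))
  if (nlevels(f) != 2L) abort("`groups` must have exactly two levels.")
  idx1 <- which(f == levels(f)[1L])
  idx2 <- which(f == levels(f)[2L])
  if (length(idx1) < 2L || length(idx2) < 2L) {
    abort("Each group needs >= 2 samples.")
  }

  m1 <- m[, idx1, drop = FALSE]
  m2 <- m[, idx2, drop = FALSE]
  n1 <- rowSums(!is.na(m1))
  n2 <- rowSums(!is.na(m2))
  mean1 <- rowMeans(m1, na.rm = TRUE)
  mean2 <- rowMeans(m2, na.rm = TRUE)
  ss1 <- rowSums((m1 - mean1)^2, na.rm = TRUE)
  ss2 <- rowSums((m2 - mean2)^2, na.rm = TRUE)
  d <- pmax(n1 + n2 - 2, 0)
  s2 <- ifelse(d > 0, (ss1 + ss2) / pmax(d, 1), NA_real_)

  if (is.null(params)) {
    d_typical <- median(d[d > 0])
    params <- fit_moderation(s2[d == d_typical & is.finite(s2)], d_typical)
  }
  d0 <- params$d0
  s0_sq <- params$s0_sq
  s2_tilde <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
    (d0 * s0_sq + d * s2) / (d0 + d)
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  diff <- mean1 - mean2
  t_mod <- ifelse(se > 0, diff / se, 0)
  df_total <- pmin(d0 + d, 1e6)
  p <- 2 * pt(abs(t_mod), df = df_total, lower.tail = FALSE)
  p[se == 0] <- 1
  fdr <- p.adjust(p, method = "BH")

  out <- tibble(
    probe_id = rownames(m) %||% as.character(seq_len(nrow(m))),
    n1 = unname(n1), n2 = unname(n2),
    mean_diff = unname(diff),
    pooled_sd = unname(sqrt(s2)),
    moderated_t = unname(t_mod),
    df_total = unname(df_total),
    p = unname(p), fdr = unname(fdr),
    is_dmc = unname(fdr < fdr_threshold)
  )
  attr(out, "moderation") <- params
  attr(out, "contrast") <- paste(levels(f)[1L], "-", levels(f)[2L])
  class(out) <- c("dmc_result", class(out))
  out
}

#' Call differentially methylated CpGs between mutation groups
#'
#' Convenience wrapper: logit-transforms betas to M-values, forms the
#' two-group contrast from a 0/1 mutation flag in the clinical table
#' (carriers minus non-carriers) and runs [moderated_t_test()].
#'
#' @param beta Beta matrix.
#' @param clinical Clinical tibble with `sample_id` and the flag column.
#' @param group_col Name of the 0/1 mutation flag column.
#' @param fdr_threshold DMC threshold (default 0.05).
#' @param epsilon M-value clipping constant.
#' @return A `dmc_result` tibble (see [moderated_t_test()]).
#' @export
call_dmcs <- function(beta, clinical, group_col, fdr_threshold = 0.05,
                      epsilon = 0.001) {
  validate_clinical(clinical)
  if (!group_col %in% names(clinical)) {
    abort(sprintf("Column '%s' not found in clinical table.", group_col))
  }
  common <- intersect(colnames(beta), clinical$sample_id)
  flag <- clinical[[group_col]][match(common, clinical$sample_id)]
  m <- mvalue_transform(beta[, common, drop = FALSE], epsilon)
  moderated_t_test(m, factor(ifelse(flag == 1, "carrier", "non_carrier"),
                             levels = c("carrier", "non_carrier")),
                   fdr_threshold = fdr_threshold)
}
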