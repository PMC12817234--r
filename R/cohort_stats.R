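# The cohort-level inferential toolbox: Mann-Whitney comparisons with BH
# adjustment, one-way ANOVA, association-outlier flagging, median
# stratification, and the mutation screen.

#' Two-sided Mann-Whitney U test
#'
#' Exact enumeration (via the exact null distribution of U) when
#' `n1 + n2 <= exact_limit` and there are no ties; otherwise the normal
#' approximation with midrank tie correction and continuity correction.
#' Group distributions of epigenetic ages are typically non-normal, which is
#' why this test is the package-wide two-group comparison.
#'
#' @param a,b Numeric vectors (each non-empty).
#' @param exact_limit Largest `n1 + n2` for the exact method (default 12).
#' @return List `U` (statistic for `a` vs `b`), `p` (two-sided), `method`.
#' @export
mann_whitney <- function(a, b, exact_limit = 12L) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L) abort("Both groups must be non-empty.")
  has_ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- (length(a) + length(b)) <= exact_limit && !has_ties
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = use_exact,
                correct = TRUE)
  )
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (use_exact) "exact" else "normal_approx")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' `q_(i) = min_{j >= i} (p_(j) * m / j)`, capped at 1, original order
#' restored.
#'
#' @param pvals Numeric p-values in \[0, 1\].
#' @return Adjusted p-values, same order.
#' @export
benjamini_hochberg <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(pvals, method = "BH")
}

#' Flag association outliers from a simple linear fit
#'
#' Fits `y = a + b x` by least squares and flags observations whose
#' absolute residual exceeds `sd_multiplier` times the residual standard
#' deviation.
#'
#' @param x,y Numeric vectors (>= 3 complete observations).
#' @param sd_multiplier Threshold multiplier (default 2).
#' @param ids Optional observation IDs (default positional indices).
#' @return Tibble `id`, `x`, `y`, `residual`, `is_outlier`; attribute
#'   `threshold` holds the residual cutoff.
#' @export
association_outliers <- function(x, y, sd_multiplier = 2, ids = NULL) {
  assert_scalar_number(sd_multiplier, "sd_multiplier", lower = 1e-12)
  ids <- ids %||% as.character(seq_along(x))
  ok <- complete.cases(x, y)
  if (sum(ok) < 3L) abort("Association-outlier detection needs >= 3 observations.")
  if (sd(x[ok]) == 0) abort("`x` is constant; regression undefined.")
  fit <- lm(y[ok] ~ x[ok])
  res <- residuals(fit)
  # numerically perfect fits: no outliers, not machine-epsilon flags
  floor_sd <- 1e-10 * max(sd(y[ok]), 1e-300)
  thr <- sd_multiplier * max(sd(res), floor_sd)
  out <- tibble(id = ids[ok], x = x[ok], y = y[ok], residual = unname(res),
                is_outlier = abs(res) > thr)
  attr(out, "threshold") <- thr
  out
}

#' Median stratification into High/Low groups
#'
#' Values above the median are `"High"`; values at or below it are `"Low"`
#' (ties at the median deterministically assigned to Low).
#'
#' @param values Numeric vector (>= 2 values).
#' @return Character vector of `"High"`/`"Low"` labels.
#' @export
median_stratify <- function(values) {
  if (length(values) < 2L) abort("Median stratification needs >= 2 values.")
  med <- median(values, na.rm = TRUE)
  out <- ifelse(values > med, "High", "Low")
  out[is.na(values)] <- NA_character_
  out
}

#' Classical one-way ANOVA
#'
#' F over between-/within-group mean squares via the standard linear-model
#' decomposition.
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups, each
#'   with >= 2 values).
#' @return List `F`, `p`, `df_between`, `df_within`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L) abort("ANOVA needs >= 2 groups.")
  if (any(vapply(groups, length, 0L) < 2L)) abort("Each group needs >= 2 values.")
  if (all(vapply(groups, function(g) sd(g) == 0, TRUE))) {
    abort("Zero within-group variance everywhere; F undefined.")
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  tab <- anova(lm(y ~ g))
  list(F = tab$`F value`[1L], p = tab$`Pr(>F)`[1L],
       df_between = tab$Df[1L], df_within = tab$Df[2L])
}

#' Mutation screen: per-gene carrier vs non-carrier comparisons
#'
#' For every 0/1 mutation flag column (`*_mut`) in the clinical table with
#' at least `min_carriers` carriers, compares the supplied per-sample values
#' (epigenetic age or acceleration) between carriers and non-carriers with
#' a two-sided Mann-Whitney test and BH-adjusts across the tested genes.
#' Genes below the carrier floor are reported as screened out (no test).
#'
#' @param clinical Clinical tibble with `sample_id` and `*_mut` flag
#'   columns.
#' @param values Named numeric vector, sample_id -> value to compare.
#' @param min_carriers Carrier floor; genes need `>= min_carriers` carriers
#'   to enter the test family (default 3, i.e. carrier number > 2).
#' @param genes Optional character vector restricting the screen (column
#'   names without the `_mut` suffix).
#' @return Tibble `gene`, `n_carriers`, `n_noncarriers`, `U`, `p`, `p_adj`,
#'   `screened_out`, sorted by `p_adj`.
#' @export
mutation_screen <- function(clinical, values, min_carriers = 3L, genes = NULL) {
  validate_clinical(clinical)
  min_carriers <- assert_count(min_carriers, "min_carriers", 1L)
  flag_cols <- grep("_mut$", names(clinical), value = TRUE)
  if (!is.null(genes)) flag_cols <- intersect(paste0(genes, "_mut"), flag_cols)
  if (length(flag_cols) == 0L) abort("No `*_mut` flag columns to screen.")
  v <- values[clinical$sample_id]

  rows <- purrr::map(flag_cols, function(col) {
    flag <- clinical[[col]]
    ok <- !is.na(flag) & !is.na(v)
    carriers <- v[ok & flag == 1]
    noncar <- v[ok & flag == 0]
    screened <- length(carriers) < min_carriers
    if (screened || length(noncar) == 0L) {
      tibble(gene = sub("_mut$", "", col), n_carriers = length(carriers),
             n_noncarriers = length(noncar), U = NA_real_, p = NA_real_,
             screened_out = TRUE)
    } else {
      mw <- mann_whitney(carriers, noncar)
      tibble(gene = sub("_mut$", "", col), n_carriers = length(carriers),
             n_noncarriers = length(noncar), U = mw$U, p = mw$p,
             screened_out = FALSE)
    }
  })
  out <- bind_rows(rows)
  out$p_adj <- NA_real_
  tested <- !out$screened_out
  out$p_adj[tested] <- benjamini_hochberg(out$p[tested])
  arrange(out, .data$screened_out, .data$p_adj, .data$gene)
}
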