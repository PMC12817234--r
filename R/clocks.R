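# Linear epigenetic clocks and age acceleration.

#' Apply a linear clock to a beta matrix
#'
#' Per sample i, the linear predictor is
#' `s_i = intercept + sum_g w_g * beta_{g,i}` over the clock's CpGs, followed
#' by the clock's calibration into years. Clocks flagged
#' `requires_normalization` expect BMIQ-normalized betas; this function does
#' not normalize — pair it with [bmiq_normalize_matrix()] upstream (the
#' causality-enriched clocks consume raw betas).
#'
#' @param beta Beta matrix (probes x samples).
#' @param clock A [clock_definition()].
#' @param missing_policy `"error"` (default): abort if any clock CpG is
#'   absent or missing; `"mean_impute"`: absent/missing CpG values are
#'   replaced by the cohort mean of the available samples at that CpG, and
#'   the imputed count is reported.
#' @return Tibble `sample_id`, `clock`, `linear_predictor`,
#'   `epigenetic_age`; attribute `n_imputed` records imputed CpG count.
#' @export
apply_clock <- function(beta, clock, missing_policy = c("error", "mean_impute")) {
  missing_policy <- match.arg(missing_policy)
  validate_beta_matrix(beta)
  stopifnot(inherits(clock, "clock_definition"))

  cpgs <- names(clock$weights)
  absent <- setdiff(cpgs, rownames(beta))
  sub <- matrix(NA_real_, length(cpgs), ncol(beta),
                dimnames = list(cpgs, colnames(beta)))
  present <- intersect(cpgs, rownames(beta))
  sub[present, ] <- beta[present, , drop = FALSE]

  n_missing_cells <- sum(is.na(sub))
  if (n_missing_cells > 0L && missing_policy == "error") {
    if (length(absent) > 0L) {
      abort(sprintf("Clock '%s': %d CpG(s) absent from the matrix: %s%s",
                    clock$name, length(absent),
                    paste(head(absent, 5), collapse = ", "),
                    if (length(absent) > 5) ", ..." else ""))
    }
    abort(sprintf("Clock '%s': missing beta values at clock CpGs under policy 'error'.",
                  clock$name))
  }
  n_imputed <- 0L
  if (n_missing_cells > 0L) {
    row_means <- rowMeans(sub, na.rm = TRUE)
    row_means[is.nan(row_means)] <- 0.5  # CpG absent everywhere: neutral beta
    idx <- which(is.na(sub), arr.ind = TRUE)
    sub[idx] <- row_means[idx[, 1L]]
    n_imputed <- nrow(idx)
  }

  s <- clock$intercept + as.numeric(crossprod(sub, clock$weights[cpgs]))
  ea <- calibrate_age(s, clock)
  out <- tibble(
    sample_id = colnames(beta),
    clock = clock$name,
    linear_predictor = s,
    epigenetic_age = ea
  )
  attr(out, "n_imputed") <- n_imputed
  out
}

#' Calibrate a clock linear predictor into years
#'
#' Identity calibration returns the predictor unchanged. The
#' `log_linear_adult` mode inverts the pan-tissue-style forward transform
#' `F(age) = log(age + 1) - log(adult_age + 1)` for `age <= adult_age` and
#' `F(age) = (age - adult_age) / (adult_age + 1)` above it:
#' a predictor `s < 0` maps to `exp(s) * (adult_age + 1) - 1`, and `s >= 0`
#' maps to `s * (adult_age + 1) + adult_age`. Continuous and strictly
#' increasing, with `calibrate(F(a)) = a`.
#'
#' @param s Numeric linear predictor(s).
#' @param clock A [clock_definition()] (supplies mode and `adult_age`), or a
#'   character mode with `adult_age` given separately.
#' @param adult_age Adult-age knot in years, used when `clock` is a mode
#'   string (default 20).
#' @return Ages in years.
#' @export
calibrate_age <- function(s, clock = "identity", adult_age = 20) {
  if (inherits(clock, "clock_definition")) {
    mode <- clock$calibration
    adult_age <- clock$adult_age
  } else {
    mode <- match.arg(clock, c("identity", "log_linear_adult"))
  }
  if (mode == "identity") return(s)
  ifelse(s < 0, exp(s) * (adult_age + 1) - 1, s * (adult_age + 1) + adult_age)
}

#' Forward pan-tissue-style age transform
#'
#' `F(age) = log(age + 1) - log(adult_age + 1)` for `age <= adult_age`, else
#' `(age - adult_age) / (adult_age + 1)`. Inverse of
#' [calibrate_age()] in `log_linear_adult` mode.
#'
#' @param age Ages in years (> -1).
#' @param adult_age Adult-age knot in years (default 20).
#' @return Transformed values.
#' @export
age_transform <- function(age, adult_age = 20) {
  ifelse(age <= adult_age,
         log(age + 1) - log(adult_age + 1),
         (age - adult_age) / (adult_age + 1))
}

#' Epigenetic age acceleration as the difference from chronological age
#'
#' `EAA = epigenetic_age - chronological_age`. The difference method is used
#' deliberately: in leukemic cohorts the epigenetic-age/chronological-age
#' relation is not linear, so residuals from a fitted regression would be an
#' unreliable acceleration measure.
#'
#' @param ea Tibble from [apply_clock()] (needs `sample_id`,
#'   `epigenetic_age`).
#' @param clinical Clinical tibble with `sample_id`, `age_years`.
#' @return `ea` joined with `chronological_age` and `eaa`; samples without a
#'   chronological age are dropped with a warning carrying the count.
#' @export
compute_eaa <- function(ea, clinical) {
  validate_clinical(clinical)
  out <- ea %>%
    left_join(select(clinical, sample_id = "sample_id",
                     chronological_age = "age_years"),
              by = "sample_id")
  n_missing <- sum(is.na(out$chronological_age))
  if (n_missing > 0L) {
    warn(sprintf("%d sample(s) without chronological age skipped.", n_missing))
    out <- filter(out, !is.na(.data$chronological_age))
  }
  mutate(out, eaa = .data$epigenetic_age - .data$chronological_age)
}
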