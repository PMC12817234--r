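# Cohort QC and normalization.

#' Iterative PCA-based cohort outlier filter
#'
#' Screens a methylation cohort for outlying samples along the first
#' principal component. Per iteration: (1) probes are mean-centred (no
#' scaling: betas share the common \[0,1\] scale) and PC1 sample scores are
#' computed; (2) each sample's squared distance from the cohort mean along
#' PC1 is converted to a z-score; (3) one-sided upper-tail p-values
#' `1 - pnorm(z)` (only large squared distances indicate outliers) are
#' Benjamini-Hochberg adjusted; (4) samples with adjusted p below
#' `fdr_threshold` are removed. Iteration stops when all current z-scores lie
#' inside `z_range`, when an iteration removes nothing, or at
#' `max_iterations`.
#'
#' @param beta Beta matrix (probes x samples); probes with any missing value
#'   are dropped before PCA.
#' @param fdr_threshold BH-FDR removal threshold (default 0.2).
#' @param z_range Length-2 numeric, symmetric about 0 (default `c(-20, 20)`);
#'   the stopping band for z-scores.
#' @param max_iterations Iteration cap (default 10).
#' @return List with `kept` (filtered beta matrix) and `report`, a list
#'   holding `removed` (tibble sample_id/iteration/z/p_adj), `final_z`
#'   (tibble over kept samples), `iterations`, `status`
#'   (`"converged"`, `"no_removals"`, `"max_iterations"`, `"zero_variance"`,
#'   or `"too_few_samples"`) and `stopping_rule` (audit note: the z-score
#'   reading of the stopping band is the implemented one).
#' @export
pca_outlier_filter <- function(beta, fdr_threshold = 0.2,
                               z_range = c(-20, 20), max_iterations = 10L) {
  validate_beta_matrix(beta)
  assert_fraction(fdr_threshold, "fdr_threshold")
  if (length(z_range) != 2L || !isTRUE(all.equal(z_range[1L], -z_range[2L]))) {
    abort("`z_range` must be a symmetric interval c(-z, z).")
  }
  if (ncol(beta) < 3L) abort("PCA outlier filter needs >= 3 samples.")

  current <- beta[complete.cases(beta), , drop = FALSE]
  if (nrow(current) < 2L) abort("Too few complete probes for PCA.")
  removed <- list()
  status <- "max_iterations"
  iter <- 0L
  z <- rep(NA_real_, ncol(current))

  while (iter < max_iterations) {
    iter <- iter + 1L
    if (ncol(current) < 3L) {
      status <- "too_few_samples"
      break
    }
    centred <- current - rowMeans(current)
    # PC1 sample scores via the small samples x samples cross-product
    cp <- crossprod(centred)
    eig <- eigen(cp, symmetric = TRUE)
    if (eig$values[1L] <= 1e-12 * nrow(centred)) {
      status <- "zero_variance"
      warn("Zero variance along PC1; no samples removed.")
      z <- rep(0, ncol(current))
      break
    }
    scores <- eig$vectors[, 1L] * sqrt(eig$values[1L])
    d2 <- (scores - mean(scores))^2
    if (sd(d2) == 0) {
      status <- "zero_variance"
      z <- rep(0, ncol(current))
      break
    }
    z <- (d2 - mean(d2)) / sd(d2)
    p <- 1 - pnorm(z)
    p_adj <- p.adjust(p, method = "BH")
    drop <- which(p_adj < fdr_threshold)
    if (length(drop) > 0L) {
      removed[[iter]] <- tibble(
        sample_id = colnames(current)[drop], iteration = iter,
        z = z[drop], p_adj = p_adj[drop]
      )
      current <- current[, -drop, drop = FALSE]
      z <- z[-drop]
    }
    if (length(drop) == 0L) {
      status <- "no_removals"
      break
    }
    if (all(z >= z_range[1L] & z <= z_range[2L])) {
      status <- "converged"
      break
    }
  }

  kept <- beta[, colnames(current), drop = FALSE]
  list(
    kept = kept,
    report = list(
      removed = if (length(removed)) bind_rows(removed) else
        tibble(sample_id = character(), iteration = integer(),
               z = numeric(), p_adj = numeric()),
      final_z = tibble(sample_id = colnames(current), z = z),
      iterations = iter,
      status = status,
      stopping_rule = "all PC1 squared-distance z-scores within z_range"
    )
  )
}

#' Logit (M-value) transform of beta values
#'
#' `M = log2(b' / (1 - b'))` with `b' = clip(b, epsilon, 1 - epsilon)`;
#' clipping keeps boundary betas finite. Strictly increasing on
#' `(epsilon, 1 - epsilon)`.
#'
#' @param beta Beta matrix or numeric vector.
#' @param epsilon Clipping constant in (0, 0.5); default 0.001.
#' @return Object of the same shape on the M-value scale.
#' @export
mvalue_transform <- function(beta, epsilon = 0.001) {
  assert_scalar_number(epsilon, "epsilon", 1e-12, 0.5 - 1e-12)
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  log2(b / (1 - b))
}

#' Inverse of the M-value transform
#'
#' @param m M-values.
#' @return Beta values in (0, 1).
#' @export
mvalue_inverse <- function(m) {
  2^m / (1 + 2^m)
}
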