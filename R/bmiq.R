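# Beta-mixture quantile normalization. A three-state beta mixture
# (unmethylated / hemimethylated / methylated) is fitted to the sample and to
# the reference by EM, and the sample's values are mapped through the two
# fitted mixture CDFs: out = F_ref^{-1}(F_sample(beta)). The full-CDF map is
# strictly monotone, so within-sample rank order is preserved by
# construction, and it reduces to the identity when sample and reference
# coincide.

# Weighted method-of-moments beta fit (responsibility-weighted E/M steps).
.beta_mom <- function(x, w) {
  sw <- sum(w)
  m <- sum(w * x) / sw
  v <- sum(w * (x - m)^2) / sw
  v <- max(v, 1e-8)
  # guard against moments outside the beta-feasible set
  v <- min(v, m * (1 - m) * 0.999)
  common <- m * (1 - m) / v - 1
  c(shape1 = max(m * common, 1e-3), shape2 = max((1 - m) * common, 1e-3))
}

#' Fit a three-state beta mixture to a beta-value vector
#'
#' EM with states initialized by beta-value thresholds (<= 0.2 unmethylated,
#' 0.2-0.8 hemimethylated, >= 0.8 methylated), responsibility-weighted
#' method-of-moments M-steps, convergence on relative log-likelihood change.
#'
#' @param x Numeric vector of betas; clipped into `(eps, 1 - eps)`.
#' @param tol Relative log-likelihood tolerance (default 1e-4).
#' @param max_iter Maximum EM iterations (default 100).
#' @param eps Boundary clip (default 1e-6).
#' @return List with `pi` (mixing weights), `shape1`, `shape2` (length-3
#'   each), `loglik`, `iterations`, `converged`.
#' @export
fit_beta_mixture <- function(x, tol = 1e-4, max_iter = 100L, eps = 1e-6) {
  x <- pmin(pmax(x[!is.na(x)], eps), 1 - eps)
  if (length(x) < 10L) abort("Beta-mixture fit needs >= 10 values.")
  state <- cut(x, c(-Inf, 0.2, 0.8, Inf), labels = FALSE)
  k <- 3L
  pi_k <- vapply(1:k, function(j) max(mean(state == j), 1e-3), 0)
  pi_k <- pi_k / sum(pi_k)
  sh <- matrix(0, k, 2)
  for (j in 1:k) {
    w <- as.numeric(state == j)
    if (sum(w) < 2) w <- w + 1e-3  # near-empty state: lean on the pooled data
    sh[j, ] <- .beta_mom(x, w)
  }
  ll_old <- -Inf
  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  resp <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    dens <- vapply(1:k, function(j) pi_k[j] * dbeta(x, sh[j, 1], sh[j, 2]),
                   numeric(length(x)))
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    resp <- dens / tot
    ll <- sum(log(tot))
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    pi_k <- pmax(colMeans(resp), 1e-6)
    pi_k <- pi_k / sum(pi_k)
    for (j in 1:k) sh[j, ] <- .beta_mom(x, resp[, j])
  }
  if (!converged) {
    abort(sprintf(
      "Beta-mixture EM did not converge in %d iterations (last 5 loglik: %s).",
      max_iter, paste(signif(tail(ll_trace, 5), 8), collapse = ", ")))
  }
  list(pi = pi_k, shape1 = sh[, 1], shape2 = sh[, 2],
       loglik = ll_trace[length(ll_trace)], iterations = iter,
       converged = converged)
}

.mixture_cdf <- function(q, fit) {
  out <- 0
  for (j in 1:3) out <- out + fit$pi[j] * pbeta(q, fit$shape1[j], fit$shape2[j])
  out
}

.mixture_quantile <- function(p, fit) {
  # strictly increasing CDF on (0,1): invert by bisection (uniroot)
  vapply(p, function(pp) {
    if (pp <= 0) return(0)
    if (pp >= 1) return(1)
    uniroot(function(q) .mixture_cdf(q, fit) - pp, c(0, 1),
            tol = 1e-12)$root
  }, 0)
}

#' BMIQ-style normalization of one sample onto a reference
#'
#' Fits the three-state beta mixture to both vectors and maps the sample
#' through `F_ref^{-1}(F_sample(.))`, aligning the unmethylated,
#' hemimethylated and methylated quantiles of the sample's distribution onto
#' the reference's.
#'
#' @param sample Numeric beta vector.
#' @param reference Numeric beta vector on the identical probe set.
#' @param tol,max_iter,eps Passed to [fit_beta_mixture()].
#' @return Normalized beta vector in \[0, 1\], same length/names as `sample`;
#'   missing values propagate.
#' @export
bmiq_normalize <- function(sample, reference, tol = 1e-4, max_iter = 100L,
                           eps = 1e-6) {
  if (length(sample) != length(reference)) {
    abort("`sample` and `reference` must cover the identical probe set.")
  }
  fit_s <- fit_beta_mixture(sample, tol = tol, max_iter = max_iter, eps = eps)
  fit_r <- fit_beta_mixture(reference, tol = tol, max_iter = max_iter, eps = eps)
  ok <- !is.na(sample)
  x <- pmin(pmax(sample[ok], eps), 1 - eps)
  # map each distinct value once; monotone by construction
  ux <- sort(unique(x))
  uy <- .mixture_quantile(.mixture_cdf(ux, fit_s), fit_r)
  out <- sample
  out[ok] <- uy[match(x, ux)]
  pmin(pmax(out, 0), 1)
}

#' BMIQ-normalize a cohort beta matrix onto its median reference
#'
#' The reference is the probe-wise median sample of the cohort unless
#' supplied; each sample is normalized independently with
#' [bmiq_normalize()]. Used on the pan-tissue clock path only; the
#' causality-enriched clocks consume raw betas.
#'
#' @param beta Beta matrix (probes x samples).
#' @param reference Optional reference beta vector (length = nrow(beta)).
#' @param ... Passed to [bmiq_normalize()].
#' @return Normalized beta matrix of the same shape.
#' @export
bmiq_normalize_matrix <- function(beta, reference = NULL, ...) {
  validate_beta_matrix(beta)
  if (is.null(reference)) {
    reference <- apply(beta, 1L, median, na.rm = TRUE)
  }
  out <- vapply(seq_len(ncol(beta)),
                function(j) bmiq_normalize(beta[, j], reference, ...),
                numeric(nrow(beta)))
  dimnames(out) <- dimnames(beta)
  out
}
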