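# Shared fixtures, built in code.

no_mutations <- setNames(numeric(0), character(0))

# small AML-like cohort (mutation structure, decoys) for fast tests
small_config <- function(seed = 1L, ...) {
  args <- list(
    n_samples = 60L, n_probes = 2500L, n_age_cpgs = 100L, n_adapt_cpgs = 60L,
    n_prc2_regions = 30L, probes_per_region = 5L, n_decoy_tfs = 5L,
    n_decoy_genes = 3L, seed = seed
  )
  do.call(cohort_config, modifyList(args, list(...)))
}

# control-style tight cluster: no mutation groups, no latent-age jitter
tight_config <- function(seed = 1L, ...) {
  small_config(seed = seed, mutation_fractions = no_mutations,
               prc2_mutation_shift = no_mutations, n_decoy_genes = 0L,
               bioage_jitter_sd = 0, ...)
}

# per-base coverage oracle for interval sets on a small universe
coverage_vector <- function(regions, chrom, universe_len) {
  cov <- logical(universe_len)  # base b covered iff b-1 in [start, end)
  rr <- regions[regions$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(rr))) {
    lo <- max(rr$start[i], 0) + 1L
    hi <- min(rr$end[i], universe_len)
    if (hi >= lo) cov[lo:hi] <- TRUE
  }
  cov
}

random_regions <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000L) {
  starts <- sample.int(max_pos - 2L, n, replace = TRUE)
  widths <- sample.int(200L, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = starts,
    end = pmin(starts + widths, max_pos)
  )
}

# two-sided exact Mann-Whitney p by full enumeration of group assignments
mw_permutation_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(pooled), n1)
  u_stat <- function(x, y) {
    r <- rank(c(x, y))
    sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  }
  obs <- u_stat(a, b)
  n2 <- length(b)
  mid <- n1 * n2 / 2
  us <- apply(idx, 2L, function(i) u_stat(pooled[i], pooled[-i]))
  mean(abs(us - mid) >= abs(obs - mid) - 1e-12)
}
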