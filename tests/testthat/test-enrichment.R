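# exhaustive hypergeometric oracle: enumerate all C(N, n) draws
hyper_p_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  in_set <- function(col) sum(col <= K)   # first K elements are "in the TF set"
  mean(apply(draws, 2L, in_set) >= k)
}

test_that("hypergeometric p matches exhaustive enumeration", {
  expect_equal(
    tf_enrichment(paste0("p", 1:4),
                  list(tf = paste0("p", c(1:3, 10, 11))),
                  paste0("p", 1:20), min_overlap_cpgs = 1L)$p,
    hyper_p_enum(20, 5, 4, 3), tolerance = 1e-12)

  withr::local_seed(29)
  for (i in 1:12) {
    N <- sample(8:25, 1)
    K <- sample.int(N, 1)
    n <- sample.int(N, 1)
    universe <- paste0("p", seq_len(N))
    dmc <- sample(universe, n)
    tfset <- universe[seq_len(K)]
    got <- tf_enrichment(dmc, list(tf = tfset), universe,
                         min_overlap_cpgs = 1L)
    k <- length(intersect(dmc, tfset))
    expect_equal(got$k, k)
    expect_equal(got$p, hyper_p_enum(N, K, n, k), tolerance = 1e-12)
  }
})

test_that("a TF covering the whole universe is never enriched", {
  universe <- paste0("p", 1:30)
  dmc <- paste0("p", 1:6)
  got <- tf_enrichment(dmc, list(all = universe), universe)
  expect_equal(got$k, got$n)
  expect_equal(got$p, 1)
})

test_that("the small-overlap exclusion keeps TFs out of the BH family", {
  universe <- paste0("p", 1:100)
  dmc <- paste0("p", 1:10)
  sets <- list(big = paste0("p", 1:20), tiny = paste0("p", c(1, 2, 3, 99)))
  got <- tf_enrichment(dmc, sets, universe, min_overlap_cpgs = 5L)
  expect_true(got$excluded[got$tf == "tiny"])
  expect_true(is.na(got$fdr[got$tf == "tiny"]))
  # excluded TF does not change the tested TF's FDR (m = 1 here)
  expect_equal(got$fdr[got$tf == "big"], got$p[got$tf == "big"])
  # k-based exclusion variant
  got_k <- tf_enrichment(dmc, sets, universe, min_overlap_cpgs = 4L,
                         exclude_on = "dmc_overlap")
  expect_true(got_k$excluded[got_k$tf == "tiny"])   # k = 3 < 4

  # relabeling probes leaves enrichment unchanged (set cardinalities only)
  perm <- setNames(paste0("q", 1:100), universe)
  got_perm <- tf_enrichment(unname(perm[dmc]),
                            lapply(sets, function(s) unname(perm[s])),
                            unname(perm[universe]), min_overlap_cpgs = 5L)
  expect_equal(got_perm$p, got$p)
  expect_error(tf_enrichment(character(0), sets, universe), "Empty DMC")
})

test_that("planted DMCs rank the PRC2 subunits top-2 among decoys", {
  sim <- generate_cohort(small_config(seed = 91, n_samples = 200L,
                                      n_decoy_tfs = 10L))
  dmc <- call_dmcs(sim$beta, sim$clinical, "DNMT3A_mut")
  sets <- lapply(sim$layout$peaks, function(pk) {
    map_probes(sim$layout$manifest, pk)$probe_id
  })
  enr <- tf_enrichment(dmc$probe_id[dmc$is_dmc], sets,
                       universe = rownames(sim$beta))
  tested <- enr[!enr$excluded, ]
  expect_setequal(tested$tf[1:2], c("EZH2", "SUZ12"))
  expect_true(all(tested$fdr[1:2] < 0.05))
})

test_that("partial correlation: residual method equals the closed form", {
  withr::local_seed(8)
  for (i in 1:10) {
    x <- rnorm(30); z <- rnorm(30)
    y <- 0.5 * x + 0.3 * z + rnorm(30)
    closed <- (cor(x, y) - cor(x, z) * cor(y, z)) /
      sqrt((1 - cor(x, z)^2) * (1 - cor(y, z)^2))
    expect_equal(partial_pearson(x, y, z), closed, tolerance = 1e-10)
  }
  # orthogonal control: partial equals plain Pearson
  x <- rnorm(40); y <- x + rnorm(40)
  z <- residuals(lm(rnorm(40) ~ x + y))   # orthogonal to both by construction
  expect_equal(partial_pearson(x, y, z), cor(x, y), tolerance = 1e-10)
  # y identical to the control: degenerate
  expect_error(partial_pearson(rnorm(10), z <- rnorm(10), z), "zero residual")
})

test_that("EA/TF-methylation correlation ranks the planted signal first", {
  withr::local_seed(3)
  n <- 80
  age <- runif(n, 20, 80)
  signal <- age + rnorm(n, 0, 10)
  ea <- tibble::tibble(sample_id = sprintf("S%02d", 1:n), clock = "adapt",
                       linear_predictor = signal, epigenetic_age = signal)
  clin <- tibble::tibble(sample_id = ea$sample_id, age_years = age)
  scores <- dplyr::bind_rows(
    tibble::tibble(sample_id = ea$sample_id, set_name = "planted",
                   mean_beta = 0.2 + 0.004 * signal + rnorm(n, 0, 0.01),
                   n_cpgs_used = 5L),
    purrr::map(1:6, function(i) {
      tibble::tibble(sample_id = ea$sample_id,
                     set_name = sprintf("decoy%02d", i),
                     mean_beta = runif(n, 0.2, 0.6), n_cpgs_used = 5L)
    })
  )
  got <- ea_tf_methylation_correlation(scores, ea, clin, top_k = 3L)
  expect_equal(got$tf[1], "planted")
  expect_true(got$top[1])
  # perfectly aligned EA and score with independent age: r = 1
  scores1 <- tibble::tibble(sample_id = ea$sample_id, set_name = "self",
                            mean_beta = signal / 100, n_cpgs_used = 1L)
  got1 <- ea_tf_methylation_correlation(scores1, ea, clin)
  expect_equal(got1$partial_r, 1, tolerance = 1e-10)
})
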