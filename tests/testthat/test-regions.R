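test_that("intersection matches a per-base oracle on random sets", {
  withr::local_seed(23)
  a <- random_regions(200)
  b <- random_regions(200)
  got <- intersect_region_sets(a, b)
  for (chrom in c("chr1", "chr2")) {
    cov <- coverage_vector(got, chrom, 11000L)
    oracle <- coverage_vector(a, chrom, 11000L) &
      coverage_vector(b, chrom, 11000L)
    expect_identical(cov, oracle)
  }
  # disjoint sets intersect to nothing
  d1 <- tibble::tibble(chrom = "chr1", start = 0, end = 10)
  d2 <- tibble::tibble(chrom = "chr1", start = 10, end = 20)
  expect_equal(nrow(intersect_region_sets(d1, d2)), 0L)
  # self-intersection is the identity on disjoint inputs
  self <- intersect_region_sets(d1, d1)
  expect_equal(self$start, d1$start)
  expect_equal(self$end, d1$end)
})

test_that("TSS annotation respects half-open boundaries", {
  regions <- tibble::tibble(chrom = "chr1", start = c(10, 100), end = c(20, 200))
  # TSS at region start is inside; at the end coordinate it is not
  got <- annotate_tss(regions, tibble::tibble(chrom = "chr1", pos = c(10, 200)))
  expect_identical(got$is_tss, c(TRUE, FALSE))

  withr::local_seed(3)
  rr <- random_regions(100)
  tss <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 300, TRUE),
                        pos = sample.int(10500L, 300, TRUE))
  got2 <- annotate_tss(rr, tss)
  oracle <- vapply(seq_len(nrow(rr)), function(i) {
    any(tss$chrom == rr$chrom[i] & tss$pos >= rr$start[i] & tss$pos < rr$end[i])
  }, TRUE)
  expect_identical(got2$is_tss, oracle)
})

test_that("promoter windows follow strand and clip at zero", {
  tss <- tibble::tibble(chrom = "chr1", pos = c(5000, 1000), strand = "+")
  got <- promoter_windows(tss)
  expect_equal(got$start, c(0, 2000))
  expect_equal(got$end, c(1200, 5200))
  # minus strand mirrors the window
  minus <- promoter_windows(tibble::tibble(chrom = "chr1", pos = 5000,
                                           strand = "-"))
  expect_equal(minus$start, 5000 - 200)
  expect_equal(minus$end, 5000 + 3000)
})

test_that("probe mapping matches brute-force containment", {
  withr::local_seed(41)
  rr <- random_regions(60)
  rr$region_id <- sprintf("r%02d", seq_len(nrow(rr)))
  mf <- tibble::tibble(probe_id = sprintf("cg%03d", 1:200),
                       chrom = sample(c("chr1", "chr2"), 200, TRUE),
                       pos = sample.int(10500L, 200, TRUE))
  got <- map_probes(mf, rr)
  oracle <- do.call(rbind, lapply(seq_len(nrow(mf)), function(i) {
    hit <- rr$chrom == mf$chrom[i] & rr$start <= (mf$pos[i] - 1) &
      (mf$pos[i] - 1) < rr$end
    if (any(hit)) data.frame(probe_id = mf$probe_id[i],
                             region_id = rr$region_id[hit])
  }))
  expect_equal(nrow(got), nrow(oracle))
  key <- function(d) sort(paste(d$probe_id, d$region_id))
  expect_identical(key(got), key(oracle))

  # half-open boundary: 1-based pos 20 is 0-based 19, inside [10,20) is FALSE
  rr1 <- tibble::tibble(chrom = "c", start = 10, end = 20, region_id = "r")
  mf1 <- tibble::tibble(probe_id = c("in", "out"), chrom = "c", pos = c(16, 21))
  got1 <- map_probes(mf1, rr1)
  expect_identical(got1$probe_id, "in")
  expect_identical(attr(got1, "unplaced"), "out")
})

test_that("region methylation score is an exact mean and order-invariant", {
  withr::local_seed(5)
  beta <- matrix(runif(40), 8, 5,
                 dimnames = list(sprintf("cg%02d", 1:8), sprintf("S%d", 1:5)))
  probes <- c("cg03", "cg01", "cg07")
  got <- region_methylation_score(beta, probes, "x")
  oracle <- vapply(seq_len(5), function(j) {
    s <- 0
    for (p in probes) s <- s + beta[p, j]
    s / length(probes)
  }, 0)
  expect_equal(got$mean_beta, oracle, tolerance = 1e-12)
  expect_equal(region_methylation_score(beta, rev(probes), "x")$mean_beta,
               got$mean_beta)
  expect_equal(got$n_cpgs_used, rep(3L, 5), ignore_attr = TRUE)

  flat <- matrix(0.5, 4, 3, dimnames = list(paste0("p", 1:4), paste0("s", 1:3)))
  expect_equal(region_methylation_score(flat, rownames(flat))$mean_beta,
               rep(0.5, 3))
  single <- region_methylation_score(beta, "cg02", "one")
  expect_equal(single$mean_beta, unname(beta["cg02", ]))
  expect_error(region_methylation_score(beta, "nope", "bad"), "zero member")

  # missing values: excluded sample-wise and counted
  beta2 <- beta
  beta2["cg01", "S2"] <- NA
  got2 <- region_methylation_score(beta2, probes, "x")
  expect_equal(got2$n_cpgs_used[2], 2L, ignore_attr = TRUE)
  expect_equal(got2$mean_beta[2], mean(beta2[c("cg03", "cg07"), "S2"]))
})

test_that("LMC stratification is flat on flat data with balanced groups", {
  cfg <- small_config(seed = 1)
  lay <- generate_regions(cfg)
  beta <- matrix(0.2, cfg$n_probes, 23,
                 dimnames = list(lay$manifest$probe_id, sprintf("S%03d", 1:23)))
  gv <- setNames(seq_len(23), colnames(beta))
  got <- lmc_stratification(beta, lay$prc2_regions, lay$manifest, gv,
                            n_groups = 7L, n_region_bins = 3L)
  expect_true(all(abs(got$mean_beta - 0.2) < 1e-12))
  sizes <- unique(got$n_samples)
  expect_lte(max(sizes) - min(sizes), 1L)
  expect_equal(sum(got$n_samples[got$region_bin == 1]), 23L)

  expect_error(
    lmc_stratification(beta, lay$prc2_regions, lay$manifest, gv,
                       n_region_bins = 1000L),
    "reduce n_region_bins")
})

test_that("adaptive-age grouping orders LMC methylation; age grouping is weaker", {
  sim <- generate_cohort(small_config(seed = 14, n_samples = 140L))
  prc2 <- sim$layout$prc2_regions
  ea <- apply_clock(sim$beta, truth_clock(sim, "adaptive"))
  by_ea <- lmc_stratification(
    sim$beta, prc2, sim$layout$manifest,
    setNames(ea$epigenetic_age, ea$sample_id), n_region_bins = 3L)
  # monotone non-decreasing across groups within every bin
  for (b in unique(by_ea$region_bin)) {
    cells <- by_ea$mean_beta[by_ea$region_bin == b][order(by_ea$group[by_ea$region_bin == b])]
    expect_true(all(diff(cells) >= -1e-9))
  }
  ages <- setNames(sim$clinical$age_years, sim$clinical$sample_id)
  by_age <- lmc_stratification(sim$beta, prc2, sim$layout$manifest, ages,
                               n_region_bins = 3L)
  bg_var <- function(df) mean(tapply(df$mean_beta, df$region_bin, var))
  expect_gt(bg_var(by_ea), bg_var(by_age))
})
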