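test_that("identical seeds give identical cohorts; config errors are caught", {
  cfg <- small_config(seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$beta, b$beta)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)

  expect_error(small_config(mutation_fractions = c(A = 0.7, B = 0.6),
                            prc2_mutation_shift = c(A = -0.1, B = 0.1)),
               "sum to <= 1")
  expect_error(small_config(n_probes = 100L), "probes needed")
  expect_error(small_config(n_outlier_samples = 100L), "exceed")
})

test_that("noise-free drivers are exactly linear in the planted ages", {
  cfg <- small_config(seed = 9, noise_sd = 0, bioage_jitter_sd = 0)
  sim <- generate_cohort(cfg)
  age <- sim$clinical$age_years
  # every age CpG: beta difference between samples == slope * age difference
  sub <- sim$beta[sim$truth$probe_roles$age, ]
  for (g in c(1L, 25L, 100L)) {
    expect_equal(sub[g, ] - sub[g, 1],
                 cfg$age_slope * (age - age[1]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # two samples 50 years apart differ by exactly 0.10 at age_slope 0.002
  i <- which.min(age); j <- which.min(abs(age - (age[i] + 50)))
  expect_equal(unname(sub[1, j] - sub[1, i]), 0.002 * (age[j] - age[i]),
               tolerance = 1e-12)
})

test_that("noise-free PRC2 group shifts equal the planted shifts exactly", {
  cfg <- small_config(seed = 4, noise_sd = 0, bioage_jitter_sd = 0)
  sim <- generate_cohort(cfg)
  grp <- sim$truth$group
  prc2 <- sim$beta[sim$truth$probe_roles$prc2, ]
  # remove the bioage-driven part, which is identical across groups probe-wise
  resid <- sweep(prc2, 2L,
                 cfg$prc2_gain_per_unit_bioage * sim$truth$bioage, "-")
  for (lb in names(cfg$mutation_fractions)) {
    diff <- mean(resid[, grp == lb]) - mean(resid[, grp == "WT"])
    expect_equal(diff, cfg$prc2_mutation_shift[[lb]], tolerance = 1e-12)
  }
})

test_that("with noise, group mean shifts approach planted values (3xSE)", {
  cfg <- small_config(seed = 77, n_samples = 500L)
  sim <- generate_cohort(cfg)
  grp <- sim$truth$group
  membership <- sim$truth$region_membership
  prc2m <- region_methylation_score(sim$beta, membership$probe_id, "PRC2")
  resid <- prc2m$mean_beta -
    cfg$prc2_gain_per_unit_bioage * sim$truth$bioage[prc2m$sample_id]
  for (lb in names(cfg$mutation_fractions)) {
    d <- resid[grp == lb]
    w <- resid[grp == "WT"]
    diff <- mean(d) - mean(w)
    se <- sqrt(var(d) / length(d) + var(w) / length(w))
    expect_lt(abs(diff - cfg$prc2_mutation_shift[[lb]]), 3 * se)
  }
})

test_that("truth is complete: planted entities exist in the emitted data", {
  cfg <- small_config(seed = 8, n_outlier_samples = 4L)
  sim <- generate_cohort(cfg)
  expect_length(sim$truth$outlier_samples, 4L)
  expect_true(all(sim$truth$outlier_samples %in% colnames(sim$beta)))
  expect_true(all(sim$truth$dmc_probes %in% rownames(sim$beta)))
  expect_setequal(sim$truth$dmc_probes,
                  c(sim$truth$probe_roles$adapt, sim$truth$probe_roles$prc2))
  expect_true(all(sim$truth$probe_roles$prc2 %in%
                    sim$truth$region_membership$probe_id))
  expect_setequal(
    unique(sim$truth$region_membership$region_id),
    sim$layout$prc2_regions$region_id
  )
  expect_true(all(sim$beta >= 0 & sim$beta <= 1))
})

test_that("EZH2/SUZ12 peak intersection recovers exactly the planted regions", {
  cfg <- small_config(seed = 2, n_prc2_regions = 5L)
  lay <- generate_regions(cfg)
  got <- intersect_region_sets(lay$peaks$EZH2, lay$peaks$SUZ12)
  expect_equal(nrow(got), 5L)
  expect_equal(got$start, lay$prc2_regions$start)
  expect_equal(got$end, lay$prc2_regions$end)

  # a probe planted inside a PRC2 region maps back to that region
  mm <- map_probes(lay$manifest, lay$prc2_regions)
  first_probe <- lay$probe_roles$prc2[1]
  expect_equal(mm$region_id[mm$probe_id == first_probe], "prc2_1")
})

test_that("manifest positions are covered only by the intended peaks", {
  withr::local_seed(13)
  cfg <- small_config(seed = 13)
  lay <- generate_regions(cfg)
  roles <- lay$probe_roles
  intended <- c(
    setNames(rep(list(c("EZH2", "SUZ12")), length(roles$prc2)), roles$prc2),
    setNames(rep(list(character(0)), length(roles$age)), roles$age)
  )
  # brute-force containment check per probe over every peak set
  for (pid in c(sample(roles$prc2, 10), sample(roles$age, 5),
                sample(roles$background, 10))) {
    pos0 <- lay$manifest$pos[lay$manifest$probe_id == pid] - 1L
    covering <- names(Filter(function(pk) {
      any(pk$start <= pos0 & pos0 < pk$end)
    }, lay$peaks))
    if (pid %in% names(intended)) {
      expect_setequal(covering, intended[[pid]])
    } else {
      # background probes: covered by at most one decoy TF
      expect_lte(length(setdiff(covering, c("EZH2", "SUZ12"))), 1L)
      expect_false(any(c("EZH2", "SUZ12") %in% covering))
    }
  }
})

test_that("truth clocks reproduce planted drivers", {
  # single-CpG identity clock: EA equals that probe's beta
  beta <- matrix(c(0.5, 0.25), 1, 2, dimnames = list("cg1", c("a", "b")))
  cl <- clock_definition("one", 0, c(cg1 = 1))
  ea <- apply_clock(beta, cl)
  expect_equal(ea$epigenetic_age, c(0.5, 0.25))

  # planted adaptive clock: EA tracks the adaptive score, r > 0.9 at n=200
  sim <- generate_cohort(small_config(seed = 21, n_samples = 200L))
  ea2 <- apply_clock(sim$beta, truth_clock(sim, "adaptive"))
  expect_gt(cor(ea2$epigenetic_age,
                sim$truth$adaptive_score[ea2$sample_id]), 0.9)
})

test_that("a written cohort reads back unchanged", {
  sim <- generate_cohort(small_config(seed = 6, n_samples = 20L,
                                      n_probes = 400L, n_age_cpgs = 20L,
                                      n_adapt_cpgs = 20L, n_prc2_regions = 8L,
                                      n_decoy_tfs = 3L))
  dir <- withr::local_tempdir()
  write_cohort(sim, dir)
  expect_equal(read_beta_matrix(file.path(dir, "beta.tsv")), sim$beta,
               tolerance = 1e-12)
  cl <- read_clock(file.path(dir, "clock_synthetic_adaptage.csv"))
  ref <- truth_clock(sim, "adaptive")
  expect_equal(cl$weights, ref$weights)
  expect_equal(cl$intercept, ref$intercept)
  mf <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(mf$probe_id, sim$layout$manifest$probe_id)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_setequal(unlist(truth$dmc_probes), sim$truth$dmc_probes)
})
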