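# Seeded synthetic 450K-style cohort generator. The generator plants, with
# known truth, every piece of statistical structure the downstream stages
# assume: age-drifting CpGs, adaptive-clock CpGs decoupled from
# chronological age, PRC2-bound low-methylated regions gaining methylation
# with biological age and shifted by mutation group, global-shift cohort
# outliers, decoy TF peaks and decoy mutation flags, and survival times tied
# to the planted adaptive score.

#' Synthetic cohort configuration
#'
#' Defaults emulate a TCGA-LAML-like cohort: 194 samples, DNMT3A-like
#' carriers at 47/194 and IDH2-like carriers at 18/194, ages spanning adult
#' life, a PRC2-target compartment starting low-methylated and gaining
#' ~0.002 beta units per year of biological age, DNMT3A-like carriers
#' shifted down and IDH2-like carriers shifted up at PRC2 targets, and a
#' 2.5-fold hazard contrast between Low and High planted-adaptive-score
#' groups. Probe count defaults to a 12k downsample of a 450K layout.
#'
#' @param n_samples,n_probes Cohort dimensions.
#' @param age_range Chronological-age range in years, `c(min, max)`.
#' @param n_age_cpgs CpGs drifting linearly with latent biological age.
#' @param age_slope Drift in beta units per year.
#' @param n_adapt_cpgs CpGs drifting with the planted adaptive score
#'   (biological age plus mutation shift); disjoint from PRC2 regions, as
#'   adaptive-clock CpGs overlap PRC2 targets only minimally in real data.
#' @param n_prc2_regions,probes_per_region PRC2 region compartment size.
#' @param prc2_baseline_beta Baseline methylation of PRC2 regions.
#' @param prc2_gain_per_unit_bioage Beta-units gained per year of
#'   biological age at PRC2 probes.
#' @param mutation_fractions Named fractions of carriers per mutation label
#'   (remainder is wild-type); must sum to <= 1.
#' @param prc2_mutation_shift Named beta-unit shifts applied at PRC2 probes
#'   per mutation label (negative DNMT3A-like, positive IDH2-like).
#' @param n_decoy_tfs Decoy TF peak sets over background probes.
#' @param n_decoy_genes,decoy_gene_fraction Decoy mutation flags,
#'   independent of everything.
#' @param n_outlier_samples,outlier_shift Planted global-mean-shift cohort
#'   outliers.
#' @param noise_sd Per-value Gaussian noise in beta units.
#' @param bioage_jitter_sd SD (years) of the latent biological-age jitter
#'   around chronological age; 0 makes the drivers fully deterministic.
#' @param survival_hazard_ratio_high_vs_low_adapt Hazard ratio of the Low
#'   over the High planted-adaptive group (High survives longer).
#' @param median_survival_months Median survival of the Low group.
#' @param censoring_rate Approximate fraction censored.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 194L,
                          n_probes = 12000L,
                          age_range = c(20, 90),
                          n_age_cpgs = 500L,
                          age_slope = 0.002,
                          n_adapt_cpgs = 300L,
                          n_prc2_regions = 200L,
                          probes_per_region = 5L,
                          prc2_baseline_beta = 0.12,
                          prc2_gain_per_unit_bioage = 0.002,
                          mutation_fractions = c(DNMT3A = 47 / 194, IDH2 = 18 / 194),
                          prc2_mutation_shift = c(DNMT3A = -0.05, IDH2 = 0.05),
                          n_decoy_tfs = 10L,
                          n_decoy_genes = 6L,
                          decoy_gene_fraction = 0.12,
                          n_outlier_samples = 0L,
                          outlier_shift = 0.15,
                          noise_sd = 0.02,
                          bioage_jitter_sd = 5,
                          survival_hazard_ratio_high_vs_low_adapt = 2.5,
                          median_survival_months = 12,
                          censoring_rate = 0.3,
                          seed = 1L) {
  cfg <- list(
    n_samples = assert_count(n_samples, "n_samples", 3L),
    n_probes = assert_count(n_probes, "n_probes", 1L),
    age_range = age_range,
    n_age_cpgs = assert_count(n_age_cpgs, "n_age_cpgs", 0L),
    age_slope = assert_scalar_number(age_slope, "age_slope"),
    n_adapt_cpgs = assert_count(n_adapt_cpgs, "n_adapt_cpgs", 0L),
    n_prc2_regions = assert_count(n_prc2_regions, "n_prc2_regions", 1L),
    probes_per_region = assert_count(probes_per_region, "probes_per_region", 1L),
    prc2_baseline_beta = assert_fraction(prc2_baseline_beta, "prc2_baseline_beta"),
    prc2_gain_per_unit_bioage =
      assert_scalar_number(prc2_gain_per_unit_bioage, "prc2_gain_per_unit_bioage"),
    mutation_fractions = mutation_fractions,
    prc2_mutation_shift = prc2_mutation_shift,
    n_decoy_tfs = assert_count(n_decoy_tfs, "n_decoy_tfs", 0L),
    n_decoy_genes = assert_count(n_decoy_genes, "n_decoy_genes", 0L),
    decoy_gene_fraction = assert_fraction(decoy_gene_fraction, "decoy_gene_fraction"),
    n_outlier_samples = assert_count(n_outlier_samples, "n_outlier_samples", 0L),
    outlier_shift = assert_scalar_number(outlier_shift, "outlier_shift"),
    noise_sd = assert_scalar_number(noise_sd, "noise_sd", 0),
    bioage_jitter_sd = assert_scalar_number(bioage_jitter_sd, "bioage_jitter_sd", 0),
    survival_hazard_ratio_high_vs_low_adapt =
      assert_scalar_number(survival_hazard_ratio_high_vs_low_adapt,
                           "survival_hazard_ratio_high_vs_low_adapt", 1e-8),
    median_survival_months =
      assert_scalar_number(median_survival_months, "median_survival_months", 1e-8),
    censoring_rate = assert_fraction(censoring_rate, "censoring_rate"),
    seed = assert_count(seed, "seed")
  )
  if (length(cfg$age_range) != 2L || cfg$age_range[1L] <= 0 ||
      cfg$age_range[1L] > cfg$age_range[2L]) {
    abort("`age_range` must be c(min, max) with 0 < min <= max.")
  }
  if (any(cfg$mutation_fractions < 0 | cfg$mutation_fractions > 1)) {
    abort("All mutation fractions must lie in [0, 1].")
  }
  if (sum(cfg$mutation_fractions) > 1 + 1e-12) {
    abort("`mutation_fractions` must sum to <= 1.")
  }
  if (!setequal(names(cfg$mutation_fractions), names(cfg$prc2_mutation_shift))) {
    abort("`prc2_mutation_shift` must be named like `mutation_fractions`.")
  }
  needed <- cfg$n_age_cpgs + cfg$n_adapt_cpgs +
    cfg$n_prc2_regions * cfg$probes_per_region + cfg$n_decoy_tfs * 8L
  if (cfg$n_probes < needed) {
    abort(sprintf("`n_probes` (%d) < probes needed for planted structure (%d).",
                  cfg$n_probes, needed))
  }
  if (cfg$n_outlier_samples > cfg$n_samples) {
    abort("`n_outlier_samples` cannot exceed `n_samples`.")
  }
  structure(cfg, class = "cohort_config")
}

probe_ids_for <- function(n) sprintf("cg%08d", seq_len(n))

#' Generate the genomic layout: probe manifest, TF peaks, TSS list
#'
#' Probes are placed at unique 1-based positions 1000 bp apart on a single
#' synthetic chromosome. PRC2 regions cover `probes_per_region` consecutive
#' probes each; the EZH2-like and SUZ12-like peak sets each extend a PRC2
#' region on one flank only, so their base-wise intersection recovers
#' exactly the planted regions. Decoy TF peaks cover disjoint clusters of
#' background probes. Every second PRC2 region carries a TSS inside it.
#'
#' @param config A [cohort_config()].
#' @return List `manifest` (tibble), `peaks` (named list of region tibbles:
#'   `EZH2`, `SUZ12`, `TF01`, ...), `tss` (tibble `chrom`, `pos`, `strand`),
#'   `prc2_regions` (region tibble with `region_id`), `probe_roles`
#'   (named list of probe-ID vectors: age, adapt, prc2, background).
#' @export
generate_regions <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_probes
  ids <- probe_ids_for(n)
  pos <- 1000L * seq_len(n)  # 1-based
  manifest <- tibble(probe_id = ids, chrom = "chrS1", pos = pos)

  i_age <- seq_len(config$n_age_cpgs)
  i_adapt <- seq_len(config$n_adapt_cpgs) + config$n_age_cpgs
  n_prc2_probes <- config$n_prc2_regions * config$probes_per_region
  i_prc2 <- seq_len(n_prc2_probes) + config$n_age_cpgs + config$n_adapt_cpgs
  i_bg <- setdiff(seq_len(n), c(i_age, i_adapt, i_prc2))

  region_of <- rep(seq_len(config$n_prc2_regions), each = config$probes_per_region)
  prc2 <- tibble(probe_idx = i_prc2, region = region_of) %>%
    group_by(.data$region) %>%
    summarise(start = min(pos[.data$probe_idx]) - 1L - 100L,
              end = max(pos[.data$probe_idx]) + 100L,
              .groups = "drop")
  prc2_regions <- tibble(chrom = "chrS1", start = prc2$start, end = prc2$end,
                         region_id = paste0("prc2_", prc2$region))

  ezh2 <- tibble(chrom = "chrS1", start = prc2$start - 50L, end = prc2$end,
                 score = 100)
  suz12 <- tibble(chrom = "chrS1", start = prc2$start, end = prc2$end + 50L,
                  score = 100)

  peaks <- list(EZH2 = ezh2, SUZ12 = suz12)
  if (config$n_decoy_tfs > 0L) {
    per_decoy <- 8L
    for (t in seq_len(config$n_decoy_tfs)) {
      idx <- i_bg[seq_len(per_decoy) + (t - 1L) * per_decoy]
      peaks[[sprintf("TF%02d", t)]] <- tibble(
        chrom = "chrS1",
        start = min(pos[idx]) - 1L - 100L,
        end = max(pos[idx]) + 100L,
        score = 50
      )
    }
  }

  tss_regions <- which(seq_len(config$n_prc2_regions) %% 2L == 1L)
  tss <- tibble(chrom = "chrS1",
                pos = prc2$start[tss_regions] + 150L,  # 0-based, inside region
                strand = "+")

  list(
    manifest = manifest,
    peaks = peaks,
    tss = tss,
    prc2_regions = prc2_regions,
    probe_roles = list(age = ids[i_age], adapt = ids[i_adapt],
                       prc2 = ids[i_prc2], background = ids[i_bg])
  )
}

#' Generate a seeded synthetic methylation cohort
#'
#' Draws chronological ages uniformly over `age_range`; latent biological
#' age adds Gaussian jitter (`bioage_jitter_sd`); the planted adaptive
#' score adds the mutation-group PRC2 shift expressed in bioage-equivalent
#' years. Age CpGs drift with biological age at `age_slope`; adaptive CpGs
#' drift with the adaptive score; PRC2 probes start at the region baseline
#' and gain `prc2_gain_per_unit_bioage` per year of biological age plus the
#' group shift; background probes are bimodal (two-component beta mixture
#' of low/high-methylation modes). Gaussian noise is added everywhere and
#' betas clipped to \[0, 1\]. Planted outlier samples receive a global mean
#' shift. Survival times are exponential with the configured hazard ratio
#' between Low and High planted-adaptive-score groups plus independent
#' exponential censoring.
#'
#' @param config A [cohort_config()].
#' @return List of class `synthetic_cohort`: `beta` (matrix), `clinical`
#'   (tibble), `layout` (the [generate_regions()] output), `truth` (list:
#'   `bioage`, `adaptive_score`, `group`, `outlier_samples`, `dmc_probes`,
#'   `probe_roles`, `region_membership`, `age_cpg_baseline`,
#'   `adapt_cpg_baseline`, `adaptive_group`), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, .generate_cohort_impl(config))
}

.generate_cohort_impl <- function(config) {
  n <- config$n_samples
  layout <- generate_regions(config)
  roles <- layout$probe_roles
  ids <- layout$manifest$probe_id
  sample_ids <- sprintf("S%04d", seq_len(n))

  # stratified uniform: ages evenly cover the range (cohort-design emulation),
  # one sample per 1/n stratum, in random order
  age <- config$age_range[1L] + (sample.int(n) - runif(n)) / n *
    (config$age_range[2L] - config$age_range[1L])
  bioage <- age + if (config$bioage_jitter_sd > 0)
    rnorm(n, 0, config$bioage_jitter_sd) else 0

  # mutation groups with deterministic carrier counts, randomly placed
  labels <- names(config$mutation_fractions)
  counts <- round(config$mutation_fractions * n)
  while (sum(counts) > n) counts[which.max(counts)] <- counts[which.max(counts)] - 1L
  group <- rep("WT", n)
  pool <- sample.int(n)
  at <- 0L
  for (lb in labels) {
    if (counts[[lb]] > 0L) {
      group[pool[at + seq_len(counts[[lb]])]] <- lb
      at <- at + counts[[lb]]
    }
  }

  shift_beta <- setNames(rep(0, n), sample_ids)
  shift_years <- rep(0, n)
  for (lb in labels) {
    is_lb <- group == lb
    shift_beta[is_lb] <- config$prc2_mutation_shift[[lb]]
    shift_years[is_lb] <- if (config$prc2_gain_per_unit_bioage != 0)
      config$prc2_mutation_shift[[lb]] / config$prc2_gain_per_unit_bioage else 0
  }
  adaptive_score <- bioage + shift_years

  beta <- matrix(0, config$n_probes, n, dimnames = list(ids, sample_ids))

  # age CpGs: per-probe baseline + slope * biological age
  if (length(roles$age) > 0L) {
    base_age <- runif(length(roles$age), 0.05, 0.30)
    beta[roles$age, ] <- outer(base_age, rep(1, n)) +
      outer(rep(config$age_slope, length(roles$age)), bioage)
  } else base_age <- numeric(0)

  # adaptive CpGs: per-probe baseline + slope * adaptive score
  if (length(roles$adapt) > 0L) {
    base_adapt <- runif(length(roles$adapt), 0.05, 0.30)
    beta[roles$adapt, ] <- outer(base_adapt, rep(1, n)) +
      outer(rep(config$age_slope, length(roles$adapt)), adaptive_score)
  } else base_adapt <- numeric(0)

  # PRC2 probes: region baseline + gain * bioage + group shift
  region_baseline <- config$prc2_baseline_beta +
    runif(config$n_prc2_regions, 0, 0.10)
  probe_region <- rep(seq_len(config$n_prc2_regions),
                      each = config$probes_per_region)
  prc2_vals <- outer(region_baseline[probe_region], rep(1, n)) +
    outer(rep(config$prc2_gain_per_unit_bioage, length(roles$prc2)), bioage) +
    matrix(shift_beta, length(roles$prc2), n, byrow = TRUE)
  beta[roles$prc2, ] <- prc2_vals

  # background probes: bimodal baselines, constant across samples
  if (length(roles$background) > 0L) {
    lowmode <- runif(length(roles$background)) < 0.55
    base_bg <- ifelse(lowmode,
                      rbeta(length(roles$background), 2, 18),
                      rbeta(length(roles$background), 18, 2))
    beta[roles$background, ] <- outer(base_bg, rep(1, n))
  }

  if (config$noise_sd > 0) {
    beta <- beta + matrix(rnorm(length(beta), 0, config$noise_sd),
                          nrow(beta), ncol(beta))
  }

  outlier_samples <- character(0)
  if (config$n_outlier_samples > 0L) {
    oi <- sample.int(n, config$n_outlier_samples)
    beta[, oi] <- beta[, oi] + config$outlier_shift
    outlier_samples <- sample_ids[oi]
  }
  beta <- pmin(pmax(beta, 0), 1)

  # survival: High planted-adaptive group has 1/HR the Low-group hazard
  adaptive_group <- median_stratify(adaptive_score)
  hr <- config$survival_hazard_ratio_high_vs_low_adapt
  base_hazard <- log(2) / config$median_survival_months
  hazard <- ifelse(adaptive_group == "High", base_hazard / hr, base_hazard)
  event_time <- rexp(n, rate = hazard)
  os_months <- event_time
  os_event <- rep(1L, n)
  if (config$censoring_rate > 0) {
    cens_rate <- base_hazard * config$censoring_rate / (1 - config$censoring_rate)
    cens_time <- rexp(n, rate = cens_rate)
    os_event <- as.integer(event_time <= cens_time)
    os_months <- pmin(event_time, cens_time)
  }

  clinical <- tibble(
    sample_id = sample_ids,
    age_years = age,
    sex = sample(c("F", "M"), n, replace = TRUE),
    mutation_group = group,
    karyotype_normal = rbinom(n, 1, 0.5),
    risk_group = sample(c("favorable", "intermediate", "poor"), n,
                        replace = TRUE, prob = c(0.3, 0.5, 0.2)),
    os_months = os_months,
    os_event = os_event
  )
  for (lb in names(config$mutation_fractions)) {
    clinical[[paste0(lb, "_mut")]] <- as.integer(group == lb)
  }
  if (config$n_decoy_genes > 0L) {
    decoy_names <- c("FLT3", "NPM1", "TP53", "TET2", "IDH1", "NRAS",
                     sprintf("GENE%02d", seq_len(max(0, config$n_decoy_genes - 6L))))
    for (g in head(decoy_names, config$n_decoy_genes)) {
      clinical[[paste0(g, "_mut")]] <- rbinom(n, 1, config$decoy_gene_fraction)
    }
  }

  membership <- map_probes(layout$manifest, layout$prc2_regions)
  truth <- list(
    bioage = setNames(bioage, sample_ids),
    adaptive_score = setNames(adaptive_score, sample_ids),
    group = setNames(group, sample_ids),
    adaptive_group = setNames(adaptive_group, sample_ids),
    outlier_samples = outlier_samples,
    # mutation-differential probes: PRC2 probes carry the group beta shift,
    # adaptive CpGs carry it via the shifted adaptive score
    dmc_probes = c(roles$adapt, roles$prc2),
    probe_roles = roles,
    region_membership = membership,
    age_cpg_baseline = setNames(base_age, roles$age),
    adapt_cpg_baseline = setNames(base_adapt, roles$adapt),
    region_baseline = setNames(region_baseline,
                               paste0("prc2_", seq_len(config$n_prc2_regions)))
  )
  structure(list(beta = beta, clinical = clinical, layout = layout,
                 truth = truth, config = config),
            class = "synthetic_cohort")
}

#' Build an exact clock from the generator's truth
#'
#' Constructs a linear clock over the planted CpGs whose epigenetic age
#' reproduces the planted driver exactly in the noise-free limit:
#' weights `1/(k * age_slope)` over the k planted CpGs and intercept
#' `-mean(baseline)/age_slope`, so `EA = driver + noise_mean/age_slope`.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param target `"adaptive"` (AdaptAge-like; tracks the planted adaptive
#'   score) or `"age"` (tracks latent biological age).
#' @param name Clock name (defaults to `"synthetic_adaptage"` /
#'   `"synthetic_ageclock"`).
#' @return A [clock_definition()] with identity calibration.
#' @export
truth_clock <- function(cohort, target = c("adaptive", "age"), name = NULL) {
  target <- match.arg(target)
  stopifnot(inherits(cohort, "synthetic_cohort"))
  slope <- cohort$config$age_slope
  if (slope == 0) abort("Cannot build a truth clock with age_slope = 0.")
  base <- if (target == "adaptive") cohort$truth$adapt_cpg_baseline else
    cohort$truth$age_cpg_baseline
  if (length(base) == 0L) abort("No planted CpGs for this target.")
  k <- length(base)
  clock_definition(
    name = name %||% if (target == "adaptive") "synthetic_adaptage" else
      "synthetic_ageclock",
    intercept = -sum(base) / (k * slope),
    weights = setNames(rep(1 / (k * slope), k), names(base)),
    calibration = "identity"
  )
}

#' Write a synthetic cohort to a directory
#'
#' Emits `beta.tsv`, `clinical.tsv`, `manifest.tsv`, `tss.tsv`, one
#' `peaks_<TF>.bed` per TF, `clock_<name>.csv` for the truth clocks, and
#' `truth.json`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_beta_matrix(cohort$beta, file.path(dir, "beta.tsv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_manifest(cohort$layout$manifest, file.path(dir, "manifest.tsv"))
  readr::write_tsv(cohort$layout$tss, file.path(dir, "tss.tsv"), progress = FALSE)
  for (tf in names(cohort$layout$peaks)) {
    write_bed(cohort$layout$peaks[[tf]], file.path(dir, sprintf("peaks_%s.bed", tf)))
  }
  for (target in c("adaptive", "age")) {
    cl <- truth_clock(cohort, target)
    write_clock(cl, file.path(dir, sprintf("clock_%s.csv", cl$name)))
  }
  truth <- cohort$truth
  truth$region_membership <- as.list(truth$region_membership)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
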