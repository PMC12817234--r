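# Workflow front-end wiring the stages into the three analysis flows:
# cohort aging (EA/EAA + survival stratification), mutation (DMC -> TF
# enrichment + mutation screen), and prc2 (PRC2m scoring, group shifts,
# age-adjusted correlations, LMC stratification). Runs are deterministic
# given the config seed and write a machine-readable summary.

#' Run an analysis workflow on a synthetic cohort
#'
#' Generates the seeded cohort described by `config` and executes one of
#' the wired workflows, writing stage outputs, a run manifest
#' (`run_manifest.json`: package version, workflow, full config) and a
#' deterministic `summary.json` into `out_dir`. Re-running with the same
#' config reproduces identical numeric outputs.
#'
#' @param config A [cohort_config()].
#' @param workflow One of `"simulate"`, `"aging"`, `"mutation"`, `"prc2"`.
#' @param out_dir Output directory (created if needed).
#' @return The summary list, invisibly; files in `out_dir`.
#' @export
run_workflow <- function(config = cohort_config(),
                         workflow = c("simulate", "aging", "mutation", "prc2"),
                         out_dir) {
  workflow <- match.arg(workflow)
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config)

  summary <- switch(workflow,
    simulate = {
      write_cohort(cohort, out_dir)
      list(workflow = "simulate",
           n_samples = ncol(cohort$beta),
           n_probes = nrow(cohort$beta),
           n_outliers_planted = length(cohort$truth$outlier_samples))
    },
    aging = .workflow_aging(cohort, out_dir),
    mutation = .workflow_mutation(cohort, out_dir),
    prc2 = .workflow_prc2(cohort, out_dir)
  )
  summary$seed <- config$seed
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(package = "methylaging",
                   version = as.character(utils::packageVersion("methylaging")),
                   workflow = workflow,
                   config = unclass(config))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

.cohort_clocks_eaa <- function(cohort) {
  clocks <- list(truth_clock(cohort, "adaptive"), truth_clock(cohort, "age"))
  purrr::map(clocks, function(cl) {
    compute_eaa(apply_clock(cohort$beta, cl, missing_policy = "mean_impute"),
                cohort$clinical)
  }) %>% bind_rows()
}

.workflow_aging <- function(cohort, out_dir) {
  qc <- pca_outlier_filter(cohort$beta)
  eaa <- .cohort_clocks_eaa(cohort)
  readr::write_tsv(eaa, file.path(out_dir, "eaa.tsv"), progress = FALSE)

  adapt <- filter(eaa, .data$clock == "synthetic_adaptage")
  marker <- setNames(adapt$epigenetic_age, adapt$sample_id)
  surv <- survival_by_median(cohort$clinical, marker)
  readr::write_tsv(surv$group, file.path(out_dir, "adaptage_groups.tsv"),
                   progress = FALSE)

  per_clock <- eaa %>%
    group_by(.data$clock) %>%
    summarise(mean_eaa = mean(.data$eaa), sd_eaa = sd(.data$eaa),
              .groups = "drop")
  list(
    workflow = "aging",
    n_samples_kept = ncol(qc$kept),
    n_samples_removed = nrow(qc$report$removed),
    mean_eaa = setNames(as.list(per_clock$mean_eaa), per_clock$clock),
    sd_eaa = setNames(as.list(per_clock$sd_eaa), per_clock$clock),
    logrank_chisq_adaptage_median = surv$logrank$chisq,
    logrank_p_adaptage_median = surv$logrank$p
  )
}

.workflow_mutation <- function(cohort, out_dir) {
  labels <- names(cohort$config$mutation_fractions)
  main_label <- labels[1L]
  dmc <- call_dmcs(cohort$beta, cohort$clinical, paste0(main_label, "_mut"))
  readr::write_tsv(tidy(dmc), file.path(out_dir, "dmc.tsv"), progress = FALSE)

  membership <- purrr::map(cohort$layout$peaks, function(pk) {
    map_probes(cohort$layout$manifest, pk)$probe_id
  })
  enr <- tf_enrichment(dmc$probe_id[dmc$is_dmc], membership,
                       universe = rownames(cohort$beta))
  readr::write_tsv(enr, file.path(out_dir, "tf_enrichment.tsv"), progress = FALSE)

  eaa <- .cohort_clocks_eaa(cohort)
  adapt <- filter(eaa, .data$clock == "synthetic_adaptage")
  screen <- mutation_screen(cohort$clinical,
                            setNames(adapt$eaa, adapt$sample_id))
  readr::write_tsv(screen, file.path(out_dir, "mutation_screen.tsv"),
                   progress = FALSE)

  tested <- filter(enr, !.data$excluded)
  list(
    workflow = "mutation",
    contrast = paste0(main_label, "_mut"),
    n_dmc = sum(dmc$is_dmc),
    top_enriched_tfs = head(tested$tf, 3L),
    top_enrichment_fdr = head(tested$fdr, 3L),
    n_significant_tfs = sum(tested$significant),
    screen_significant_genes =
      screen$gene[!screen$screened_out & !is.na(screen$p_adj) & screen$p_adj < 0.05]
  )
}

.workflow_prc2 <- function(cohort, out_dir) {
  prc2 <- build_prc2_regions(cohort$layout$peaks$EZH2, cohort$layout$peaks$SUZ12)
  prc2 <- annotate_tss(prc2, cohort$layout$tss)
  membership <- map_probes(cohort$layout$manifest, prc2)
  prc2m <- region_methylation_score(cohort$beta, membership$probe_id, "PRC2")
  readr::write_tsv(prc2m, file.path(out_dir, "prc2m.tsv"), progress = FALSE)

  scores <- setNames(prc2m$mean_beta, prc2m$sample_id)
  cl <- cohort$clinical
  shifts <- purrr::map(names(cohort$config$mutation_fractions), function(lb) {
    flag <- cl[[paste0(lb, "_mut")]]
    mw <- mann_whitney(scores[cl$sample_id[flag == 1]],
                       scores[cl$sample_id[flag == 0]])
    tibble(group = lb,
           mean_carrier = mean(scores[cl$sample_id[flag == 1]]),
           mean_noncarrier = mean(scores[cl$sample_id[flag == 0]]),
           U = mw$U, p = mw$p)
  }) %>% bind_rows()
  readr::write_tsv(shifts, file.path(out_dir, "prc2m_shifts.tsv"),
                   progress = FALSE)

  eaa <- .cohort_clocks_eaa(cohort)
  adapt <- filter(eaa, .data$clock == "synthetic_adaptage")
  ages <- setNames(cl$age_years, cl$sample_id)
  pr <- partial_pearson(scores[adapt$sample_id], adapt$epigenetic_age,
                        ages[adapt$sample_id])

  strata <- lmc_stratification(
    cohort$beta, prc2, cohort$layout$manifest,
    setNames(adapt$epigenetic_age, adapt$sample_id))
  readr::write_tsv(strata, file.path(out_dir, "lmc_strata.tsv"), progress = FALSE)

  list(
    workflow = "prc2",
    n_prc2_regions = nrow(prc2),
    n_tss_regions = sum(prc2$is_tss),
    prc2m_shift_p = setNames(as.list(shifts$p), shifts$group),
    partial_r_adaptage_prc2m = pr,
    n_lmc_regions = length(attr(strata, "lmc_regions"))
  )
}
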