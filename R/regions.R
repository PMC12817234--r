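# Genomic-interval engine: PRC2 target construction, TSS/promoter
# annotation, probe-to-region mapping, region methylation scores, and the
# aging stratification of PRC2-bound low-methylated regions. Region sets are
# tibbles (chrom, start, end, ...) in 0-based half-open coordinates;
# GenomicRanges does the interval algebra internally.

regions_to_granges <- function(regions) {
  validate_regions(regions)
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    # IRanges is 1-based closed; BED [start, end) -> [start+1, end]
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
}

granges_to_regions <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  ) %>% arrange(.data$chrom, .data$start, .data$end)
}

#' Base-wise intersection of two region sets
#'
#' Returns the set of bases covered by both inputs, as maximal intervals.
#' Used to build PRC2 binding regions as the overlap of EZH2 and SUZ12 peak
#' sets.
#'
#' @param a,b Region tibbles (`chrom`, `start`, `end`; 0-based half-open).
#' @return Region tibble of the intersection, sorted.
#' @export
intersect_region_sets <- function(a, b) {
  ga <- regions_to_granges(a)
  gb <- regions_to_granges(b)
  granges_to_regions(GenomicRanges::intersect(ga, gb))
}

#' Build PRC2 binding regions from EZH2 and SUZ12 peaks
#'
#' PRC2 binding regions are defined as the genomic overlap of EZH2 and SUZ12
#' ChIP-seq peak sets (the two core PRC2 subunits).
#'
#' @param ezh2,suz12 Peak tibbles (`chrom`, `start`, `end`).
#' @return Region tibble with a `region_id` column (`prc2_1`, ...).
#' @export
build_prc2_regions <- function(ezh2, suz12) {
  out <- intersect_region_sets(ezh2, suz12)
  mutate(out, region_id = paste0("prc2_", row_number()))
}

#' Flag regions containing a transcription start site
#'
#' A region is a TSS region iff at least one TSS position lies within
#' `[start, end)`.
#'
#' @param regions Region tibble.
#' @param tss Tibble with `chrom`, `pos` (0-based TSS base position).
#' @return `regions` with a logical `is_tss` column.
#' @export
annotate_tss <- function(regions, tss) {
  validate_regions(regions)
  gr <- regions_to_granges(regions)
  gt <- GenomicRanges::GRanges(tss$chrom,
                               IRanges::IRanges(start = tss$pos + 1L, width = 1L))
  hits <- GenomicRanges::countOverlaps(gr, gt)
  mutate(regions, is_tss = hits > 0L)
}

#' Promoter windows around transcription start sites
#'
#' Plus-strand: `[pos - upstream, pos + downstream)`; minus-strand:
#' `[pos - downstream, pos + upstream)`; clipped at 0. Defaults follow the
#' common promoter convention of 3000 bp upstream / 200 bp downstream.
#'
#' @param tss Tibble with `chrom`, `pos` (0-based) and optional `strand`
#'   (`"+"`/`"-"`; missing treated as `"+"`).
#' @param upstream,downstream Window extents in bp.
#' @return Region tibble.
#' @export
promoter_windows <- function(tss, upstream = 3000, downstream = 200) {
  assert_scalar_number(upstream, "upstream", 0)
  assert_scalar_number(downstream, "downstream", 0)
  strand <- if ("strand" %in% names(tss)) tss$strand else rep("+", nrow(tss))
  strand[is.na(strand)] <- "+"
  plus <- strand != "-"
  start <- ifelse(plus, tss$pos - upstream, tss$pos - downstream)
  end <- ifelse(plus, tss$pos + downstream, tss$pos + upstream)
  tibble(chrom = tss$chrom, start = pmax(start, 0), end = end) %>%
    filter(.data$end > .data$start) %>%
    arrange(.data$chrom, .data$start, .data$end)
}

#' Map probes to the regions containing them
#'
#' Each probe (1-based manifest position, treated as the half-open
#' single-base interval `[pos - 1, pos)`) is assigned to every region whose
#' interval contains it.
#'
#' @param manifest Tibble `probe_id`, `chrom`, `pos` (1-based).
#' @param regions Region tibble; a `region_id` column is used when present,
#'   otherwise regions are identified by row index.
#' @return Tibble `probe_id`, `region_id`, one row per (probe, containing
#'   region); attribute `unplaced` lists probes contained by no region.
#' @export
map_probes <- function(manifest, regions) {
  validate_regions(regions)
  region_id <- if ("region_id" %in% names(regions)) regions$region_id else
    as.character(seq_len(nrow(regions)))
  gp <- GenomicRanges::GRanges(manifest$chrom,
                               IRanges::IRanges(start = manifest$pos, width = 1L))
  gr <- regions_to_granges(regions)
  hits <- GenomicRanges::findOverlaps(gp, gr)
  out <- tibble(
    probe_id = manifest$probe_id[S4Vectors::queryHits(hits)],
    region_id = region_id[S4Vectors::subjectHits(hits)]
  )
  attr(out, "unplaced") <- setdiff(manifest$probe_id, out$probe_id)
  out
}

#' Mean methylation over a region set, per sample
#'
#' The region methylation score (e.g. PRC2m for PRC2 binding regions) is the
#' unweighted mean beta over all member CpGs, per sample. Missing member
#' betas are excluded sample-wise and the number of CpGs actually used is
#' recorded.
#'
#' @param beta Beta matrix.
#' @param probes Character vector of member probe IDs (e.g. the `probe_id`
#'   column of [map_probes()] output).
#' @param set_name Label for the region set (default `"region_set"`).
#' @return Tibble `sample_id`, `set_name`, `mean_beta`, `n_cpgs_used`.
#' @export
region_methylation_score <- function(beta, probes, set_name = "region_set") {
  validate_beta_matrix(beta)
  probes <- unique(probes)
  member <- intersect(probes, rownames(beta))
  if (length(member) == 0L) {
    abort(sprintf("Region set '%s' has zero member CpGs in the matrix.", set_name))
  }
  sub <- beta[member, , drop = FALSE]
  tibble(
    sample_id = colnames(beta),
    set_name = set_name,
    mean_beta = unname(colMeans(sub, na.rm = TRUE)),
    n_cpgs_used = unname(colSums(!is.na(sub)))
  )
}

#' Stratify PRC2-bound low-methylated regions across age groups
#'
#' Reproduces the aging-stratification view of PRC2-bound low-methylated
#' CpG regions (LMCs): (1) LMC regions are the PRC2 regions whose
#' cohort-reference mean beta (mean over member probes of the probe-wise
#' cohort median) is below `lmc_beta_threshold`; (2) LMC regions are ranked
#' ascending by reference mean beta and split into `n_region_bins`
#' equal-count bins; (3) samples are ranked by the grouping variable
#' (chronological age or an epigenetic age) and split into `n_groups`
#' equal-size groups (remainder assigned to the oldest groups); (4) each
#' cell is the mean beta over that group's samples and that bin's member
#' CpGs.
#'
#' @param beta Beta matrix.
#' @param regions PRC2 region tibble (with `region_id`).
#' @param manifest Probe manifest tibble.
#' @param group_values Named numeric vector, sample_id -> grouping value
#'   (chronological age in years, or epigenetic age).
#' @param n_groups Number of sample groups (default 7).
#' @param n_region_bins Number of region bins (default 5).
#' @param lmc_beta_threshold Reference-methylation cutoff defining "low
#'   methylated" (default 0.3).
#' @return Tibble `group`, `region_bin`, `mean_beta`, `n_samples`,
#'   `n_probes`; attributes `lmc_regions` (the retained region IDs) and
#'   `grouping` note the equal-count construction.
#' @export
lmc_stratification <- function(beta, regions, manifest, group_values,
                               n_groups = 7L, n_region_bins = 5L,
                               lmc_beta_threshold = 0.3) {
  validate_beta_matrix(beta)
  n_groups <- assert_count(n_groups, "n_groups", 2L)
  n_region_bins <- assert_count(n_region_bins, "n_region_bins", 1L)
  assert_fraction(lmc_beta_threshold, "lmc_beta_threshold")
  samples <- intersect(colnames(beta), names(group_values))
  if (length(samples) < n_groups) abort("Fewer samples than groups.")
  if (anyNA(group_values[samples])) {
    abort("Grouping variable missing for some samples.")
  }

  membership <- map_probes(manifest, regions)
  membership <- filter(membership, .data$probe_id %in% rownames(beta))
  if (nrow(membership) == 0L) abort("No PRC2 region probes present in the matrix.")

  ref <- apply(beta[, samples, drop = FALSE], 1L, median, na.rm = TRUE)
  region_ref <- membership %>%
    mutate(ref_beta = ref[.data$probe_id]) %>%
    group_by(.data$region_id) %>%
    summarise(ref_mean = mean(.data$ref_beta, na.rm = TRUE), .groups = "drop")

  lmc <- region_ref %>%
    filter(.data$ref_mean < lmc_beta_threshold) %>%
    arrange(.data$ref_mean, .data$region_id)
  if (nrow(lmc) < n_region_bins) {
    abort(sprintf(
      "Only %d LMC regions below threshold %.3g but %d bins requested; reduce n_region_bins.",
      nrow(lmc), lmc_beta_threshold, n_region_bins))
  }
  lmc$region_bin <- ceiling(seq_len(nrow(lmc)) * n_region_bins / nrow(lmc))

  ord <- samples[order(group_values[samples])]
  base <- length(ord) %/% n_groups
  extra <- length(ord) %% n_groups
  sizes <- rep(base, n_groups) + c(rep(0L, n_groups - extra), rep(1L, extra))
  group_of <- rep(seq_len(n_groups), sizes)

  bin_probes <- membership %>%
    left_join(select(lmc, "region_id", "region_bin"), by = "region_id") %>%
    filter(!is.na(.data$region_bin))

  cells <- tidyr::expand_grid(group = seq_len(n_groups),
                              region_bin = seq_len(n_region_bins))
  cells$mean_beta <- NA_real_
  cells$n_samples <- sizes[cells$group]
  cells$n_probes <- NA_integer_
  for (i in seq_len(nrow(cells))) {
    g_samples <- ord[group_of == cells$group[i]]
    p <- unique(bin_probes$probe_id[bin_probes$region_bin == cells$region_bin[i]])
    cells$mean_beta[i] <- mean(beta[p, g_samples, drop = FALSE], na.rm = TRUE)
    cells$n_probes[i] <- length(p)
  }
  attr(cells, "lmc_regions") <- lmc$region_id
  attr(cells, "grouping") <-
    "equal-count sample groups by grouping variable; remainder to oldest groups"
  cells
}
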