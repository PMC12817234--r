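# Readers/writers for every file the pipeline touches. All readers validate
# hard and fail with the offending probe/sample named; all writers emit files
# their readers accept unchanged.

#' Validate a beta-value matrix
#'
#' A beta matrix is a base numeric matrix of methylation fractions with unique
#' probe IDs as rownames and unique sample IDs as colnames. Values must lie in
#' \[0, 1\]; missing values are allowed (detection failures on real arrays).
#'
#' @param beta Numeric matrix, probes x samples.
#' @return The matrix, invisibly, if valid; otherwise an error.
#' @export
validate_beta_matrix <- function(beta) {
  if (!is.matrix(beta) || !is.numeric(beta)) {
    abort("`beta` must be a numeric matrix (probes x samples).")
  }
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    abort("`beta` must carry probe IDs as rownames and sample IDs as colnames.")
  }
  if (anyDuplicated(rownames(beta))) {
    dup <- rownames(beta)[duplicated(rownames(beta))][1L]
    abort(sprintf("Duplicate probe ID in beta matrix: '%s'.", dup))
  }
  if (anyDuplicated(colnames(beta))) {
    dup <- colnames(beta)[duplicated(colnames(beta))][1L]
    abort(sprintf("Duplicate sample ID in beta matrix: '%s'.", dup))
  }
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(sprintf(
      "Beta value out of [0, 1] at probe '%s', sample '%s' (value %g).",
      rownames(beta)[bad[1L, 1L]], colnames(beta)[bad[1L, 2L]],
      beta[bad[1L, , drop = FALSE]]
    ))
  }
  invisible(beta)
}

#' Read a beta-value matrix from TSV/CSV
#'
#' Expects a header row of sample IDs and a first column of probe IDs.
#' Delimiter is inferred from the file extension (`.csv` means comma,
#' anything else tab).
#'
#' @param path File path.
#' @return Validated numeric matrix, probes x samples.
#' @export
read_beta_matrix <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim,
                          col_types = readr::cols(.default = readr::col_character()),
                          show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2L) abort("Beta matrix file needs a probe-ID column plus >= 1 sample.")
  probes <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  beta <- vapply(vals, function(col) {
    out <- suppressWarnings(as.numeric(col))
    if (any(is.na(out) & !is.na(col) & !col %in% c("NA", "")))
      abort("Non-numeric beta value in matrix file.")
    out
  }, numeric(nrow(df)))
  if (!is.matrix(beta)) beta <- matrix(beta, nrow = nrow(df),
                                       dimnames = list(NULL, names(vals)))
  rownames(beta) <- probes
  validate_beta_matrix(beta)
  beta
}

#' Write a beta-value matrix as TSV
#'
#' @param beta Validated beta matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  validate_beta_matrix(beta)
  df <- tibble::as_tibble(beta, rownames = "probe_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a BED region file
#'
#' BED3 or BED with a name and/or score column; coordinates 0-based,
#' half-open. Output intervals are sorted by (chrom, start, end). Strand is
#' ignored throughout the package: CpG methylation is strand-symmetric.
#'
#' @param path File path.
#' @return Tibble with columns `chrom`, `start`, `end` and, when present in
#'   the file, `name` and `score`.
#' @export
read_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (ncol(raw) < 3L) abort("BED file must have >= 3 tab-separated columns.")
  start <- suppressWarnings(as.numeric(raw[[2L]]))
  end <- suppressWarnings(as.numeric(raw[[3L]]))
  if (anyNA(start) || anyNA(end)) {
    abort(sprintf("Non-numeric coordinate in BED file '%s'.", path))
  }
  if (any(start >= end)) {
    i <- which(start >= end)[1L]
    abort(sprintf("BED interval with start >= end at line %d (%s:%s-%s).",
                  i, raw[[1L]][i], raw[[2L]][i], raw[[3L]][i]))
  }
  out <- tibble(chrom = raw[[1L]], start = start, end = end)
  if (ncol(raw) >= 4L) out$name <- raw[[4L]]
  if (ncol(raw) >= 5L) out$score <- suppressWarnings(as.numeric(raw[[5L]]))
  arrange(out, .data$chrom, .data$start, .data$end)
}

#' Write a region tibble as BED
#'
#' @param regions Tibble with `chrom`, `start`, `end` and optional `name`,
#'   `score` columns (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  validate_regions(regions)
  cols <- intersect(c("chrom", "start", "end", "name", "score"), names(regions))
  # BED columns are positional: a score needs a name placeholder before it
  if ("score" %in% cols && !"name" %in% cols) {
    regions$name <- "."
    cols <- c("chrom", "start", "end", "name", "score")
  }
  df <- regions[, cols, drop = FALSE]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

validate_regions <- function(regions) {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(regions))) {
    abort("Regions need `chrom`, `start`, `end` columns (0-based half-open).")
  }
  if (any(regions$start >= regions$end)) abort("Region with start >= end.")
  if (any(regions$start < 0)) abort("Region with negative start.")
  invisible(regions)
}

#' Construct a clock definition
#'
#' A clock is a named linear model over CpG betas: a scalar intercept plus a
#' weight per CpG, together with a calibration mode mapping the linear
#' predictor to years, and a flag saying whether the clock expects BMIQ-style
#' normalized betas (pan-tissue style) or raw betas (causality-enriched
#' clocks).
#'
#' @param name Clock name.
#' @param intercept Scalar intercept of the linear predictor.
#' @param weights Named numeric vector, CpG ID -> weight.
#' @param calibration `"identity"` or `"log_linear_adult"`.
#' @param adult_age Adult-age knot in years for log-linear calibration.
#' @param requires_normalization Logical; `TRUE` for pan-tissue-style clocks.
#' @return A `clock_definition` object.
#' @export
clock_definition <- function(name, intercept, weights,
                             calibration = c("identity", "log_linear_adult"),
                             adult_age = 20, requires_normalization = FALSE) {
  calibration <- match.arg(calibration)
  if (length(weights) == 0L) abort("Clock weights must be non-empty.")
  if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
    abort("Clock weights must be named by CpG ID.")
  }
  if (anyDuplicated(names(weights))) {
    abort(sprintf("Duplicate CpG ID in clock '%s': '%s'.", name,
                  names(weights)[duplicated(names(weights))][1L]))
  }
  assert_scalar_number(intercept, "intercept")
  if (calibration == "log_linear_adult") {
    assert_scalar_number(adult_age, "adult_age", lower = 1e-8)
  }
  structure(
    list(name = name, intercept = unname(intercept),
         weights = weights, calibration = calibration,
         adult_age = adult_age,
         requires_normalization = isTRUE(requires_normalization)),
    class = "clock_definition"
  )
}

#' @export
print.clock_definition <- function(x, ...) {
  cat(sprintf("<clock_definition> %s: %d CpGs, intercept %.4g, %s calibration%s\n",
              x$name, length(x$weights), x$intercept, x$calibration,
              if (x$requires_normalization) ", requires normalization" else ""))
  invisible(x)
}

#' Read a clock-coefficient CSV
#'
#' Format: `#`-prefixed `key=value` header lines carrying `name`,
#' `calibration`, `adult_age` and `requires_normalization`, then a CSV with
#' columns `cpg,weight` where the row with `cpg="(Intercept)"` holds the
#' intercept. Exactly one intercept row is required.
#'
#' @param path File path.
#' @return A [clock_definition()].
#' @export
read_clock <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), "=", fixed = TRUE)[[1L]]
    if (length(kv) == 2L) meta[[trimws(kv[1L])]] <- trimws(kv[2L])
  }
  df <- readr::read_csv(I(grep("^#", lines, value = TRUE, invert = TRUE)),
                        col_types = "cd", show_col_types = FALSE, progress = FALSE)
  if (!all(c("cpg", "weight") %in% names(df))) {
    abort("Clock CSV must have columns `cpg` and `weight`.")
  }
  is_int <- df$cpg == "(Intercept)"
  if (sum(is_int) == 0L) abort("Clock CSV is missing its '(Intercept)' row.")
  if (sum(is_int) > 1L) abort("Clock CSV has more than one '(Intercept)' row.")
  weights <- setNames(df$weight[!is_int], df$cpg[!is_int])
  clock_definition(
    name = meta$name %||% sub("\\.[^.]*$", "", basename(path)),
    intercept = df$weight[is_int],
    weights = weights,
    calibration = meta$calibration %||% "identity",
    adult_age = as.numeric(meta$adult_age %||% 20),
    requires_normalization = tolower(meta$requires_normalization %||% "false") == "true"
  )
}

#' Write a clock definition to CSV
#'
#' @param clock A [clock_definition()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clock <- function(clock, path) {
  stopifnot(inherits(clock, "clock_definition"))
  hdr <- c(
    sprintf("#name=%s", clock$name),
    sprintf("#calibration=%s", clock$calibration),
    sprintf("#adult_age=%s", format(clock$adult_age, digits = 15)),
    sprintf("#requires_normalization=%s",
            tolower(as.character(clock$requires_normalization)))
  )
  body <- c("cpg,weight",
            sprintf("(Intercept),%s", format(clock$intercept, digits = 17)),
            sprintf("%s,%s", names(clock$weights),
                    vapply(clock$weights, format, "", digits = 17)))
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

#' Read a probe manifest
#'
#' TSV with columns `probe_id`, `chrom`, `pos`; positions are 1-based
#' (array-manifest convention). For overlap arithmetic each probe is treated
#' as the 0-based half-open single-base interval `[pos - 1, pos)`.
#'
#' @param path File path.
#' @return Tibble `probe_id`, `chrom`, `pos`.
#' @export
read_manifest <- function(path) {
  df <- readr::read_tsv(path, col_types = "ccd", show_col_types = FALSE,
                        progress = FALSE)
  if (!all(c("probe_id", "chrom", "pos") %in% names(df))) {
    abort("Manifest must have columns `probe_id`, `chrom`, `pos`.")
  }
  if (anyDuplicated(df$probe_id)) {
    abort(sprintf("Duplicate probe ID in manifest: '%s'.",
                  df$probe_id[duplicated(df$probe_id)][1L]))
  }
  if (any(df$pos < 1)) abort("Manifest positions must be >= 1 (1-based).")
  df
}

#' Write a probe manifest
#' @param manifest Tibble `probe_id`, `chrom`, `pos` (1-based positions).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_tsv(manifest[, c("probe_id", "chrom", "pos")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read a clinical annotation table
#'
#' TSV with at least `sample_id` and `age_years`; typically also `sex`,
#' mutation flag columns (`*_mut`, 0/1), `karyotype_normal`, `os_months` and
#' `os_event`.
#'
#' @param path File path.
#' @return Tibble, validated.
#' @export
read_clinical <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_clinical(df)
  df
}

validate_clinical <- function(df) {
  if (!all(c("sample_id", "age_years") %in% names(df))) {
    abort("Clinical table must have `sample_id` and `age_years` columns.")
  }
  if (anyDuplicated(df$sample_id)) abort("Duplicate sample_id in clinical table.")
  if (any(!is.na(df$age_years) & df$age_years <= 0)) {
    abort("Clinical ages must be positive.")
  }
  if ("os_months" %in% names(df) && any(df$os_months < 0, na.rm = TRUE)) {
    abort("`os_months` must be >= 0.")
  }
  if ("os_event" %in% names(df) && !all(df$os_event %in% c(0, 1, NA))) {
    abort("`os_event` must be 0/1.")
  }
  invisible(df)
}

#' Write a clinical annotation table
#' @param clinical Clinical tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  validate_clinical(clinical)
  readr::write_tsv(clinical, path, progress = FALSE)
  invisible(path)
}
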