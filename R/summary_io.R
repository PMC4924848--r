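#' Canonical summary-statistic columns
#'
#' A summary-record table holds one row per SNP-trait association. The
#' canonical columns are:
#'
#' * `snp_id` — rsID
#' * `chrom` — chromosome label
#' * `effect_allele`, `other_allele` — IUPAC bases (may be `NA`; many
#'   published tables print only the trait-increasing allele)
#' * `eaf` — effect-allele frequency in `[0, 1]`
#' * `beta` — per-allele effect (SD units for a continuous trait, log-odds
#'   for a binary one)
#' * `or` — odds ratio (alternative to `beta` for binary outcomes)
#' * `ci_low`, `ci_high` — 95% CI bounds on the same scale as the effect
#' * `se` — standard error of `beta`
#' * `pvalue` — association p-value
#' * `trait`, `source` — free labels for the phenotype and the study
#'
#' At least one of `beta` / `or` must be present in a valid table.
#'
#' @return Character vector of canonical column names.
#' @export
summary_columns <- function() {
  c("snp_id", "chrom", "effect_allele", "other_allele", "eaf",
    "beta", "or", "ci_low", "ci_high", "se", "pvalue", "trait", "source")
}

#' Read a GWAS summary-statistic table
#'
#' Reads a delimited text file and normalizes its column dialect into the
#' canonical layout of [summary_columns()]. Column dialects are resolved via
#' an explicit `column_map` rather than guessed: GWAS summary formats are
#' inconsistent, and silent misreads are the dominant bug class in
#' summary-data MR.
#'
#' Unparseable numeric cells become `NA`, never zero. Row order is preserved.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping canonical names (see
#'   [summary_columns()]) to the file's column names, e.g.
#'   `c(snp_id = "SNP", beta = "Effect", se = "StdErr")`. May also be a path
#'   to a `key=value` config file (one mapping per line). `NULL` means the
#'   file already uses canonical names.
#' @param trait Trait label attached to every record.
#' @param source Study label attached to every record (ignored when the map
#'   resolves a `source` column).
#' @param delim Field delimiter; defaults to tab for `.tsv`/`.txt`, comma
#'   for `.csv`.
#' @return A tibble with the canonical columns, one row per input data row.
#' @examples
#' path <- system.file("extdata", "bmi_ms_snps.tsv", package = "summarymr")
#' bmi <- read_summary_table(
#'   path,
#'   column_map = c(snp_id = "snp_id", chrom = "chrom",
#'                  effect_allele = "effect_allele", eaf = "eaf",
#'                  beta = "beta_bmi", pvalue = "pval_bmi"),
#'   trait = "BMI", source = "GIANT")
#' @export
read_summary_table <- function(path, column_map = NULL, trait = NA_character_,
                               source = NA_character_, delim = NULL) {
  if (!file.exists(path)) {
    stop("summary table not found: ", path, call. = FALSE)
  }
  if (is.character(column_map) && length(column_map) == 1L &&
      is.null(names(column_map)) && file.exists(column_map)) {
    column_map <- read_column_map(column_map)
  }
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE,
    na = c("", "NA", "na", "."))
  if (is.null(column_map)) {
    column_map <- intersect(summary_columns(), names(raw))
    names(column_map) <- column_map
  }
  unknown <- setdiff(names(column_map), summary_columns())
  if (length(unknown) > 0) {
    stop("column_map has unknown canonical keys: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  absent <- column_map[!column_map %in% names(raw)]
  if (length(absent) > 0) {
    stop("column(s) named in column_map are missing from ", path, ": ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (!"snp_id" %in% names(column_map)) {
    stop("column_map must resolve the mandatory column: snp_id",
         call. = FALSE)
  }
  if (!any(c("beta", "or") %in% names(column_map))) {
    stop("column_map must resolve at least one effect column: beta or or",
         call. = FALSE)
  }

  numeric_cols <- c("eaf", "beta", "or", "ci_low", "ci_high", "se", "pvalue")
  out <- tibble::tibble(.rows = nrow(raw))
  for (col in summary_columns()) {
    if (col %in% names(column_map)) {
      v <- raw[[column_map[[col]]]]
      if (col %in% numeric_cols) v <- suppressWarnings(as.numeric(v))
      out[[col]] <- v
    } else {
      out[[col]] <- if (col %in% numeric_cols) NA_real_ else NA_character_
    }
  }
  if (all(is.na(out$trait))) out$trait <- trait
  if (all(is.na(out$source))) out$source <- source

  dup <- unique(out$snp_id[duplicated(out$snp_id)])
  if (length(dup) > 0) {
    stop("duplicate snp_id in ", path, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  validate_summary_records(out)
  message("read ", nrow(out), " summary records from ", path)
  out
}

#' Write a summary-record table
#'
#' Writes the canonical columns as TSV at full double precision, so that a
#' write/read round trip reproduces every non-missing value exactly.
#'
#' @param records Tibble of summary records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(records, path) {
  readr::write_tsv(records[intersect(summary_columns(), names(records))],
                   path, progress = FALSE)
  invisible(path)
}

#' Read a key=value column-map config file
#'
#' One `canonical=file_column` pair per line; blank lines and `#` comments
#' are ignored.
#'
#' @param path Path to the config file.
#' @return Named character vector usable as `column_map`.
#' @export
read_column_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  bad <- lines[!grepl("=", lines, fixed = TRUE)]
  if (length(bad) > 0) {
    stop("malformed column_map line(s): ", paste(bad, collapse = "; "),
         call. = FALSE)
  }
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  stats::setNames(vals, keys)
}

# Invariant checks shared by the readers; errors name the offending SNPs.
validate_summary_records <- function(records) {
  # rows whose effect failed to parse stay in the table as missing (they
  # are dropped by harmonization, not silently zeroed here)
  has_effect <- !is.na(records$beta) | !is.na(records$or)
  if (any(!has_effect)) {
    warning("records without any effect estimate (beta or or): ",
            paste(utils::head(records$snp_id[!has_effect], 5),
                  collapse = ", "), call. = FALSE)
  }
  bad_or <- !is.na(records$or) & records$or <= 0
  if (any(bad_or)) {
    stop("non-positive odds ratio for: ",
         paste(records$snp_id[bad_or], collapse = ", "), call. = FALSE)
  }
  ci_known <- !is.na(records$or) & !is.na(records$ci_low) &
    !is.na(records$ci_high)
  bad_ci <- ci_known & !(records$ci_low <= records$or &
                           records$or <= records$ci_high &
                           records$ci_low < records$ci_high)
  if (any(bad_ci)) {
    stop("CI does not bracket the odds ratio for: ",
         paste(records$snp_id[bad_ci], collapse = ", "), call. = FALSE)
  }
  bad_se <- !is.na(records$se) & records$se <= 0
  if (any(bad_se)) {
    stop("non-positive standard error for: ",
         paste(records$snp_id[bad_se], collapse = ", "), call. = FALSE)
  }
  bad_eaf <- !is.na(records$eaf) & (records$eaf < 0 | records$eaf > 1)
  if (any(bad_eaf)) {
    stop("allele frequency outside [0, 1] for: ",
         paste(records$snp_id[bad_eaf], collapse = ", "), call. = FALSE)
  }
  invisible(records)
}

#' Load the packaged BMI–MS instrument table
#'
#' Returns the packaged transcription of the published characteristics of
#' the 70 SNPs used as body-mass-index instruments against multiple
#' sclerosis: GIANT European sex-combined BMI effects (SD change per
#' BMI-increasing allele) and IMSGC Immunochip / IMSGC-WTCCC2 MS odds ratios
#' with 95% CIs. Thirty-six instruments were measured through proxy SNPs
#' (r-squared > 0.8 in UK10K Europeans); the remaining 34 were genotyped
#' directly, recorded here with `proxy_id = NA` and `r2 = 1`.
#'
#' All records are pre-oriented to the BMI-increasing allele, so the outcome
#' side carries no `other_allele`; harmonize with `mode = "pre_oriented"`.
#'
#' @return A list of class `"mr_fixture"` with elements
#'   * `exposure` — 70 summary records for BMI (beta scale),
#'   * `outcome` — 70 summary records for MS (OR with 95% CI),
#'   * `proxy_map` — tibble `snp_id`, `proxy_id` (`NA` when directly
#'     genotyped), `r2`, `source`.
#' @examples
#' fx <- load_bmi_ms_fixture()
#' nrow(fx$exposure)                     # 70
#' sum(!is.na(fx$proxy_map$proxy_id))    # 36
#' @export
load_bmi_ms_fixture <- function() {
  path <- system.file("extdata", "bmi_ms_snps.tsv", package = "summarymr",
                      mustWork = TRUE)
  raw <- readr::read_tsv(path, col_types = "ccccdddddddccd", progress = FALSE)
  exposure <- read_summary_table(
    path,
    column_map = c(snp_id = "snp_id", chrom = "chrom",
                   effect_allele = "effect_allele", eaf = "eaf",
                   beta = "beta_bmi", pvalue = "pval_bmi"),
    trait = "BMI", source = "GIANT")
  outcome <- read_summary_table(
    path,
    column_map = c(snp_id = "snp_id", chrom = "chrom",
                   effect_allele = "effect_allele", or = "or_ms",
                   ci_low = "or_ci_low", ci_high = "or_ci_high",
                   pvalue = "pval_ms", source = "source"),
    trait = "MS")
  proxy_map <- tibble::tibble(
    snp_id = raw$snp_id,
    proxy_id = raw$proxy_id,
    r2 = raw$proxy_r2,
    source = raw$source)
  structure(list(exposure = exposure, outcome = outcome,
                 proxy_map = proxy_map),
            class = "mr_fixture")
}

#' @export
print.mr_fixture <- function(x, ...) {
  n_proxy <- sum(!is.na(x$proxy_map$proxy_id))
  cat("BMI-MS instrument set: ", nrow(x$exposure), " SNPs (",
      n_proxy, " via proxy, ", nrow(x$exposure) - n_proxy,
      " directly genotyped)\n", sep = "")
  invisible(x)
}
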