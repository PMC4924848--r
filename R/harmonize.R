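z975 <- function() stats::qnorm(0.975)

#' Convert an odds ratio with 95% CI to log-odds and standard error
#'
#' `beta = log(or)`; `se = (log(ci_high) - log(ci_low)) / (2 * z)` with
#' `z = qnorm(0.975)`. Vectorized. [log_to_or()] is the exact inverse.
#'
#' @param or Odds ratio(s), > 0.
#' @param ci_low,ci_high 95% CI bounds on the OR scale, with
#'   `0 < ci_low <= or <= ci_high` and `ci_low < ci_high`.
#' @return A tibble with columns `beta`, `se`.
#' @examples
#' or_to_log(1.00, 0.97, 1.04)   # beta 0, se ~0.01778
#' @export
or_to_log <- function(or, ci_low, ci_high) {
  if (any(!is.finite(or) | !is.finite(ci_low) | !is.finite(ci_high))) {
    stop("or_to_log: non-finite input", call. = FALSE)
  }
  if (any(or <= 0 | ci_low <= 0 | ci_high <= 0)) {
    stop("or_to_log: odds ratios and CI bounds must be positive",
         call. = FALSE)
  }
  if (any(ci_low >= ci_high)) {
    stop("or_to_log: degenerate CI (ci_low >= ci_high)", call. = FALSE)
  }
  if (any(or < ci_low | or > ci_high)) {
    stop("or_to_log: CI does not bracket the odds ratio", call. = FALSE)
  }
  tibble::tibble(beta = log(or),
                 se = (log(ci_high) - log(ci_low)) / (2 * z975()))
}

#' Convert log-odds and SE back to an odds ratio with 95% CI
#'
#' @param beta Log-odds effect(s).
#' @param se Standard error(s), > 0.
#' @return A tibble with columns `or`, `ci_low`, `ci_high`.
#' @export
log_to_or <- function(beta, se) {
  if (any(se <= 0)) stop("log_to_or: se must be positive", call. = FALSE)
  z <- z975()
  tibble::tibble(or = exp(beta), ci_low = exp(beta - z * se),
                 ci_high = exp(beta + z * se))
}

strand_complement <- function(a) {
  chartr("ACGTacgt", "TGCAtgca", a)
}

is_palindromic <- function(a1, a2) {
  !is.na(a1) & !is.na(a2) & toupper(a2) == strand_complement(toupper(a1))
}

# Outcome effect on the log scale: prefer beta/se, else convert OR + CI.
outcome_log_effect <- function(rec) {
  beta <- rec$beta
  se <- rec$se
  need <- is.na(beta) | is.na(se)
  if (any(need)) {
    conv <- or_to_log(rec$or[need], rec$ci_low[need], rec$ci_high[need])
    beta[need] <- conv$beta
    se[need] <- conv$se
  }
  list(beta = beta, se = se)
}

# Exposure SE, reconstructed from beta and p when not reported
# (se = |beta| / z(p)); common for published instrument tables that print
# beta and p but no SE. Never used in the first-order Wald-ratio SE.
exposure_se <- function(rec) {
  se <- rec$se
  need <- is.na(se) & !is.na(rec$pvalue) & !is.na(rec$beta)
  se[need] <- abs(rec$beta[need]) /
    stats::qnorm(rec$pvalue[need] / 2, lower.tail = FALSE)
  se
}

#' Harmonize exposure and outcome records onto a shared effect allele
#'
#' Produces one harmonized instrument per SNP, with the exposure effect
#' (`beta_exposure`, SD of exposure per allele) and the outcome effect
#' (`beta_outcome`, log-odds for a binary outcome) both referring to the
#' same effect allele.
#'
#' In `"alleles"` mode both records must carry effect and other alleles:
#' if the outcome's effect allele matches the exposure's, effects are copied
#' through; if it matches the exposure's other allele (directly or after
#' strand complement), the outcome effect is negated and its allele
#' frequency complemented; otherwise harmonization fails naming the SNP.
#' Palindromic SNPs (A/T or C/G) with allele frequency in `[0.4, 0.6]`
#' cannot be resolved from alleles alone and are flagged
#' (`flag_palindromic`), never auto-dropped — the caller decides.
#'
#' In `"pre_oriented"` mode the two records are assumed already aligned to
#' the exposure-increasing allele (the layout of published instrument
#' tables that print only one allele) and effects are copied through.
#'
#' @param exposure,outcome Summary-record tibbles (see [summary_columns()])
#'   with matching `snp_id` order.
#' @param mode `"alleles"` or `"pre_oriented"`.
#' @return A tibble of harmonized instruments with columns `snp_id`,
#'   `effect_allele`, `beta_exposure`, `se_exposure`, `beta_outcome`,
#'   `se_outcome`, `eaf`, `outcome_source`, `proxy_id`, `proxy_r2`,
#'   `flag_palindromic`, `flag_af_band`, `flag_height_ld`.
#' @export
harmonize_pair <- function(exposure, outcome,
                           mode = c("alleles", "pre_oriented")) {
  mode <- match.arg(mode)
  if (nrow(exposure) != nrow(outcome)) {
    stop("exposure and outcome must have the same number of records",
         call. = FALSE)
  }
  if (!all(exposure$snp_id == outcome$snp_id)) {
    stop("snp_id mismatch between exposure and outcome; join records first",
         call. = FALSE)
  }
  out_eff <- outcome_log_effect(outcome)
  beta_out <- out_eff$beta
  se_out <- out_eff$se
  eaf <- exposure$eaf
  palindromic <- rep(FALSE, nrow(exposure))

  if (mode == "alleles") {
    need <- c(exposure$effect_allele, exposure$other_allele,
              outcome$effect_allele, outcome$other_allele)
    if (any(is.na(need))) {
      stop("alleles mode requires effect and other alleles on both sides",
           call. = FALSE)
    }
    ea_x <- toupper(exposure$effect_allele)
    oa_x <- toupper(exposure$other_allele)
    ea_y <- toupper(outcome$effect_allele)
    oa_y <- toupper(outcome$other_allele)

    same <- (ea_y == ea_x & oa_y == oa_x) |
      (ea_y == strand_complement(ea_x) & oa_y == strand_complement(oa_x))
    flipped <- (ea_y == oa_x & oa_y == ea_x) |
      (ea_y == strand_complement(oa_x) & oa_y == strand_complement(ea_x))
    # palindromic pairs satisfy both patterns; treat as same-orientation
    flipped <- flipped & !same
    bad <- !(same | flipped)
    if (any(bad)) {
      stop("irreconcilable alleles for: ",
           paste(exposure$snp_id[bad], collapse = ", "), call. = FALSE)
    }
    beta_out[flipped] <- -beta_out[flipped]
    eaf_y <- outcome$eaf
    eaf_y[flipped] <- 1 - eaf_y[flipped]
    eaf <- ifelse(is.na(eaf), eaf_y, eaf)

    pal <- is_palindromic(ea_x, oa_x)
    ambiguous_af <- !is.na(eaf) & eaf >= 0.4 & eaf <= 0.6
    palindromic <- pal & ambiguous_af
  }

  inst <- tibble::tibble(
    snp_id = exposure$snp_id,
    effect_allele = exposure$effect_allele,
    beta_exposure = exposure$beta,
    se_exposure = exposure_se(exposure),
    beta_outcome = beta_out,
    se_outcome = se_out,
    eaf = eaf,
    outcome_source = outcome$source,
    proxy_id = NA_character_,
    proxy_r2 = 1,
    flag_palindromic = palindromic,
    flag_af_band = FALSE,
    flag_height_ld = FALSE)
  validate_instruments(inst)
  inst
}

validate_instruments <- function(inst) {
  bad_se <- (!is.na(inst$se_exposure) & inst$se_exposure <= 0) |
    inst$se_outcome <= 0
  if (any(bad_se)) {
    stop("non-positive standard error for instrument(s): ",
         paste(inst$snp_id[bad_se], collapse = ", "), call. = FALSE)
  }
  # strict selection threshold is r2 > 0.8, but published tables round to
  # 2 decimals, so a printed 0.80 must validate
  if (any(inst$proxy_r2 < 0.8 & !is.na(inst$proxy_id))) {
    stop("proxy r-squared must exceed 0.8", call. = FALSE)
  }
  invisible(inst)
}

#' Flag proxied instruments in the ambiguous allele-frequency band
#'
#' Different studies report slightly different allele frequencies, so a
#' proxy whose frequency is near 0.5 is at risk of silent allele mismatch.
#' Sets `flag_af_band` for instruments that were measured through a proxy
#' AND whose effect-allele frequency lies in the closed band; directly
#' genotyped instruments are never flagged.
#'
#' @param instruments Harmonized instrument tibble.
#' @param band Closed frequency interval, default `c(0.4, 0.6)`.
#' @return `instruments` with `flag_af_band` updated.
#' @export
attach_af_band_flag <- function(instruments, band = c(0.4, 0.6)) {
  is_proxy <- !is.na(instruments$proxy_id)
  missing_af <- is.na(instruments$eaf)
  if (any(missing_af & is_proxy)) {
    warning("missing allele frequency for proxied instrument(s): ",
            paste(instruments$snp_id[missing_af & is_proxy], collapse = ", "),
            "; af-band flag not set", call. = FALSE)
  }
  instruments$flag_af_band <- is_proxy & !missing_af &
    instruments$eaf >= band[1] & instruments$eaf <= band[2]
  instruments
}

#' Harmonize the packaged BMI-MS instrument set
#'
#' Applies [harmonize_pair()] in `"pre_oriented"` mode (the table prints
#' only the BMI-increasing allele), attaches proxy provenance, and sets the
#' allele-frequency-band flag. The result is the 70-instrument set every
#' downstream estimator consumes.
#'
#' @param fixture A fixture list from [load_bmi_ms_fixture()].
#' @return Tibble of 70 harmonized instruments.
#' @examples
#' inst <- fixture_instruments()
#' sum(!is.na(inst$proxy_id))   # 36 proxied
#' @export
fixture_instruments <- function(fixture = load_bmi_ms_fixture()) {
  inst <- harmonize_pair(fixture$exposure, fixture$outcome,
                         mode = "pre_oriented")
  stopifnot(all(inst$snp_id == fixture$proxy_map$snp_id))
  inst$proxy_id <- fixture$proxy_map$proxy_id
  inst$proxy_r2 <- fixture$proxy_map$r2
  inst$outcome_source <- fixture$proxy_map$source
  attach_af_band_flag(inst)
}

#' Squared correlation between two allele-dosage vectors
#'
#' The r-squared linkage-disequilibrium measure as computed from genotype
#' dosages: the squared Pearson correlation.
#'
#' @param x,y Numeric dosage vectors of equal length (>= 3), values in
#'   `[0, 2]`, each with nonzero variance.
#' @return r-squared in `[0, 1]`.
#' @export
r2_from_dosages <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("dosage vectors must have equal length >= 3", call. = FALSE)
  }
  if (any(x < 0 | x > 2 | y < 0 | y > 2)) {
    stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in dosage vector", call. = FALSE)
  }
  min(stats::cor(x, y)^2, 1)
}

#' Pairwise LD lookup table
#'
#' A symmetric r-squared lookup keyed by unordered SNP-id pairs. An absent
#' pair means "unknown", not zero.
#'
#' @param snp_a,snp_b Character vectors of SNP ids.
#' @param r2 r-squared values in `[0, 1]`.
#' @return An object of class `"ld_table"`.
#' @export
ld_table <- function(snp_a = character(), snp_b = character(),
                     r2 = numeric()) {
  stopifnot(length(snp_a) == length(snp_b), length(snp_a) == length(r2))
  if (any(r2 < 0 | r2 > 1)) {
    stop("r-squared values must lie in [0, 1]", call. = FALSE)
  }
  key <- paste(pmin(snp_a, snp_b), pmax(snp_a, snp_b), sep = "\r")
  if (anyDuplicated(key)) {
    keep <- !duplicated(key)
    key <- key[keep]
    r2 <- r2[keep]
  }
  structure(list(r2 = stats::setNames(r2, key)), class = "ld_table")
}

#' @export
print.ld_table <- function(x, ...) {
  cat("LD table with", length(x$r2), "SNP pairs\n")
  invisible(x)
}

#' Look up pairwise r-squared
#'
#' @param ld An [ld_table()].
#' @param a,b SNP ids (vectorized).
#' @return r-squared values; `NA` where the pair is unknown.
#' @export
ld_r2 <- function(ld, a, b) {
  stopifnot(inherits(ld, "ld_table"))
  out <- unname(ld$r2[paste(pmin(a, b), pmax(a, b), sep = "\r")])
  out[a == b] <- 1
  out
}

#' Read / write an LD table as 3-column TSV
#'
#' Columns `snp_a`, `snp_b`, `r2`.
#'
#' @param path File path.
#' @return [read_ld_table()] returns an `ld_table`; [write_ld_table()]
#'   returns `path` invisibly.
#' @export
read_ld_table <- function(path) {
  d <- readr::read_tsv(path, col_types = "ccd", progress = FALSE)
  ld_table(d$snp_a, d$snp_b, d$r2)
}

#' @rdname read_ld_table
#' @param ld An `ld_table` to serialize.
#' @export
write_ld_table <- function(ld, path) {
  stopifnot(inherits(ld, "ld_table"))
  parts <- strsplit(names(ld$r2), "\r", fixed = TRUE)
  readr::write_tsv(tibble::tibble(
    snp_a = vapply(parts, `[`, "", 1),
    snp_b = vapply(parts, `[`, "", 2),
    r2 = unname(ld$r2)), path, progress = FALSE)
  invisible(path)
}

#' Greedy LD pruning of an instrument list
#'
#' Instruments must be mutually independent: a SNP correlated with another
#' instrument would double-count its signal. Candidates are ranked by
#' exposure p-value (ties broken lexicographically by SNP id) and accepted
#' greedily; a SNP is kept only if its r-squared with every already-accepted
#' SNP is at most `r2_max` or unknown. This keeps, within any correlated
#' group, the SNP most strongly associated with the exposure.
#'
#' @param snps Tibble/data frame with columns `snp_id` and `pvalue`.
#' @param ld An [ld_table()] of measured pairwise r-squared values; unknown
#'   pairs are treated as independent.
#' @param r2_max Exclusion threshold; a measured r-squared strictly greater
#'   than this drops the weaker SNP. Default 0.05.
#' @return Character vector of retained SNP ids, in acceptance order.
#' @export
ld_prune <- function(snps, ld, r2_max = 0.05) {
  if (any(is.na(snps$pvalue))) {
    stop("ld_prune requires a p-value for every SNP", call. = FALSE)
  }
  ord <- order(snps$pvalue, snps$snp_id)
  ids <- snps$snp_id[ord]
  kept <- character(0)
  for (id in ids) {
    r2 <- ld_r2(ld, rep(id, length(kept)), kept)
    if (!any(!is.na(r2) & r2 > r2_max)) kept <- c(kept, id)
  }
  kept
}

#' Find a proxy SNP in prioritized outcome sources
#'
#' When the target SNP was not genotyped in any outcome study, a highly
#' correlated stand-in is searched for. Sources are scanned in priority
#' order; if the target itself is present in a source it is its own proxy
#' (r-squared 1). Otherwise, within the first source holding any qualifying
#' candidate, the candidate with maximal r-squared strictly greater than
#' `r2_min` is chosen (ties broken by lexicographically smaller SNP id).
#'
#' @param target SNP id to represent.
#' @param sources Named list of character vectors of available SNP ids, in
#'   priority order (e.g. `list(Immunochip = ..., WTCCC2 = ...)`).
#' @param ld An [ld_table()] with measured r-squared between the target and
#'   candidates.
#' @param r2_min Strict lower bound for an acceptable proxy, default 0.8.
#' @return A list `(proxy_id, r2, source)`, or `NULL` when no source holds
#'   a qualifying proxy.
#' @export
find_proxy <- function(target, sources, ld, r2_min = 0.8) {
  stopifnot(is.list(sources), !is.null(names(sources)))
  for (src in names(sources)) {
    if (target %in% sources[[src]]) {
      return(list(proxy_id = target, r2 = 1, source = src))
    }
  }
  for (src in names(sources)) {
    cand <- setdiff(sources[[src]], target)
    if (length(cand) == 0) next
    r2 <- ld_r2(ld, rep(target, length(cand)), cand)
    ok <- !is.na(r2) & r2 > r2_min
    if (any(ok)) {
      cand <- cand[ok]
      r2 <- r2[ok]
      best <- which(r2 == max(r2))
      pick <- best[order(cand[best])][1]
      return(list(proxy_id = cand[pick], r2 = unname(r2[pick]), source = src))
    }
  }
  NULL
}
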