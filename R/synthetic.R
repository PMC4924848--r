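#' Configuration for the summary-statistic generator
#'
#' Defines the generative model for paired two-sample summary statistics
#' with known ground truth. For each SNP `j`:
#'
#' * a true exposure effect `gamma_j ~ |N(gamma_mean, gamma_sd)|`,
#' * a measured exposure effect `gamma_j + N(0, se_exposure_j)` with
#'   `se_exposure_j ~ U(se_exposure_range)`,
#' * a direct (pleiotropic) outcome effect `alpha_j` — zero for valid SNPs;
#'   for the invalid fraction, `N(0, pleio_sd)` under `"balanced"` or
#'   `N(pleio_mean, pleio_sd)` under `"directional"` pleiotropy, drawn
#'   independently of `gamma_j` so the InSIDE condition holds by
#'   construction (set `inside_violation = TRUE` to add correlation with
#'   `gamma_j` and break it),
#' * a measured outcome effect
#'   `beta_causal * gamma_j + alpha_j + N(0, se_outcome_j)` with
#'   `se_outcome_j ~ U(se_outcome_range)`.
#'
#' Outcome sampling noise is Gaussian on the log-odds scale, the standard
#' regime for summary-statistic MR of a binary outcome. The defaults mirror
#' the packaged 70-SNP BMI-MS instrument set: exposure effects with mean
#' 0.027 and SD 0.012 (SD units per allele), exposure SEs 0.003-0.005 (the
#' central 10th-90th percentile band of that set; exposure SEs in large
#' consortium meta-analyses cluster tightly just above the genome-wide
#' significance floor), outcome SEs 0.015-0.041 (log-odds), allele
#' frequencies 0.05-0.9, and about half of the instruments marked as
#' proxies.
#'
#' @param k Number of instruments (>= 3).
#' @param beta_causal True causal effect, log-odds of outcome per SD of
#'   exposure.
#' @param gamma_mean,gamma_sd Mean and SD of true exposure effects.
#' @param se_exposure_range,se_outcome_range Ranges for per-SNP SEs.
#' @param pleiotropy `"none"`, `"balanced"`, or `"directional"`.
#' @param pleio_mean Mean direct effect under directional pleiotropy.
#' @param pleio_sd SD of direct effects (balanced or directional).
#' @param prop_invalid Fraction of SNPs receiving pleiotropic effects.
#' @param eaf_range Range for simulated effect-allele frequencies.
#' @param prop_proxy Fraction of instruments marked as proxies, with
#'   r-squared drawn from `U(0.8, 1)`.
#' @param inside_violation If `TRUE`, draw `alpha_j` with correlation 0.8 to
#'   `gamma_j` among invalid SNPs, violating InSIDE (demonstrates MR-Egger
#'   failure).
#' @param seed RNG seed; `NULL` uses the current stream.
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(k = 70,
                              beta_causal = log(1.41),
                              gamma_mean = 0.027,
                              gamma_sd = 0.012,
                              se_exposure_range = c(0.003, 0.005),
                              se_outcome_range = c(0.015, 0.041),
                              pleiotropy = c("none", "balanced",
                                             "directional"),
                              pleio_mean = 0,
                              pleio_sd = 0,
                              prop_invalid = 0,
                              eaf_range = c(0.05, 0.9),
                              prop_proxy = 36 / 70,
                              inside_violation = FALSE,
                              seed = NULL) {
  pleiotropy <- match.arg(pleiotropy)
  check <- function(ok, field) {
    if (!ok) stop("invalid simulation config field: ", field, call. = FALSE)
  }
  check(is.numeric(k) && k >= 3, "k")
  check(is.numeric(beta_causal) && is.finite(beta_causal), "beta_causal")
  check(gamma_sd >= 0, "gamma_sd")
  check(length(se_exposure_range) == 2 && all(se_exposure_range >= 0) &&
          !is.unsorted(se_exposure_range), "se_exposure_range")
  check(length(se_outcome_range) == 2 && all(se_outcome_range > 0) &&
          !is.unsorted(se_outcome_range), "se_outcome_range")
  check(pleio_sd >= 0, "pleio_sd")
  check(prop_invalid >= 0 && prop_invalid <= 1, "prop_invalid")
  check(prop_proxy >= 0 && prop_proxy <= 1, "prop_proxy")
  check(length(eaf_range) == 2 && all(eaf_range >= 0 & eaf_range <= 1) &&
          !is.unsorted(eaf_range), "eaf_range")
  structure(list(k = as.integer(k), beta_causal = beta_causal,
                 gamma_mean = gamma_mean, gamma_sd = gamma_sd,
                 se_exposure_range = se_exposure_range,
                 se_outcome_range = se_outcome_range,
                 pleiotropy = pleiotropy, pleio_mean = pleio_mean,
                 pleio_sd = pleio_sd, prop_invalid = prop_invalid,
                 eaf_range = eaf_range, prop_proxy = prop_proxy,
                 inside_violation = inside_violation, seed = seed),
            class = "simulation_config")
}

#' Generate one synthetic two-sample dataset
#'
#' Draws paired summary statistics under the linear causal model described
#' in [simulation_config()] and returns them as a harmonized instrument
#' tibble together with the ground truth. Deterministic for a fixed seed;
#' the caller's RNG stream is left untouched when a seed is given.
#'
#' @param config A [simulation_config()].
#' @return A list of class `"mr_simulation"`: `instruments` (harmonized
#'   instrument tibble with `snp_id`s `snp0001`...), `truth` (list with
#'   `beta_causal`, per-SNP `alpha`, `gamma`, and logical `valid` mask), and
#'   the `config`.
#' @examples
#' ds <- generate_dataset(simulation_config(k = 10, seed = 1))
#' mr_ivw(ds$instruments)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  draw <- function() {
    k <- config$k
    gamma <- abs(stats::rnorm(k, config$gamma_mean, config$gamma_sd))
    # degenerate-at-zero draws would make Wald ratios undefined
    gamma <- pmax(gamma, 1e-6)
    se_g <- stats::runif(k, config$se_exposure_range[1],
                         config$se_exposure_range[2])
    se_G <- stats::runif(k, config$se_outcome_range[1],
                         config$se_outcome_range[2])
    n_invalid <- round(k * config$prop_invalid)
    valid <- rep(TRUE, k)
    if (n_invalid > 0) valid[sample.int(k, n_invalid)] <- FALSE
    alpha <- rep(0, k)
    if (config$pleiotropy != "none" && n_invalid > 0) {
      mu <- if (config$pleiotropy == "directional") config$pleio_mean else 0
      a <- stats::rnorm(n_invalid, mu, config$pleio_sd)
      if (config$inside_violation) {
        # tie direct effects to instrument strength (breaks InSIDE)
        g_inv <- gamma[!valid]
        scale <- if (config$gamma_sd > 0) {
          (g_inv - mean(g_inv)) / config$gamma_sd
        } else {
          rep(0, n_invalid)
        }
        a <- mu + 0.8 * config$pleio_sd * scale +
          sqrt(1 - 0.8^2) * (a - mu)
      }
      alpha[!valid] <- a
    }
    gamma_hat <- gamma + stats::rnorm(k, 0, se_g)
    Gamma_hat <- config$beta_causal * gamma + alpha +
      stats::rnorm(k, 0, se_G)
    eaf <- stats::runif(k, config$eaf_range[1], config$eaf_range[2])
    n_proxy <- round(k * config$prop_proxy)
    proxy <- rep(FALSE, k)
    if (n_proxy > 0) proxy[sample.int(k, n_proxy)] <- TRUE
    proxy_r2 <- ifelse(proxy, stats::runif(k, 0.8, 1), 1)

    ids <- sprintf("snp%04d", seq_len(k))
    inst <- tibble::tibble(
      snp_id = ids,
      effect_allele = "A",
      beta_exposure = gamma_hat,
      se_exposure = se_g,
      beta_outcome = Gamma_hat,
      se_outcome = se_G,
      eaf = eaf,
      outcome_source = "simulated",
      proxy_id = ifelse(proxy, paste0(ids, "p"), NA_character_),
      proxy_r2 = proxy_r2,
      flag_palindromic = FALSE,
      flag_af_band = FALSE,
      flag_height_ld = FALSE)
    inst <- attach_af_band_flag(inst)
    structure(list(instruments = inst,
                   truth = list(beta_causal = config$beta_causal,
                                gamma = gamma, alpha = alpha, valid = valid),
                   config = config),
              class = "mr_simulation")
  }
  if (is.null(config$seed)) draw() else local_seed(config$seed, draw())
}

#' @export
print.mr_simulation <- function(x, ...) {
  cat("simulated two-sample dataset: k =", nrow(x$instruments),
      "instruments, true effect =", signif(x$truth$beta_causal, 4),
      "(log-odds/SD),", sum(!x$truth$valid), "invalid\n")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits `exposure.tsv` and `outcome.tsv` in the canonical summary-table
#' layout (readable by [read_summary_table()]) plus `truth.json` with the
#' ground truth and proxy provenance. Two writes of the same seeded dataset
#' are byte-identical.
#'
#' @param ds An `"mr_simulation"` from [generate_dataset()].
#' @param dir Output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "mr_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  inst <- ds$instruments
  exposure <- tibble::tibble(
    snp_id = inst$snp_id, chrom = NA_character_,
    effect_allele = inst$effect_allele, other_allele = NA_character_,
    eaf = inst$eaf, beta = inst$beta_exposure, or = NA_real_,
    ci_low = NA_real_, ci_high = NA_real_, se = inst$se_exposure,
    pvalue = p_two_sided(inst$beta_exposure / inst$se_exposure),
    trait = "exposure", source = "simulated")
  outcome <- tibble::tibble(
    snp_id = inst$snp_id, chrom = NA_character_,
    effect_allele = inst$effect_allele, other_allele = NA_character_,
    eaf = inst$eaf, beta = inst$beta_outcome, or = NA_real_,
    ci_low = NA_real_, ci_high = NA_real_, se = inst$se_outcome,
    pvalue = p_two_sided(inst$beta_outcome / inst$se_outcome),
    trait = "outcome", source = "simulated")
  write_summary_table(exposure, file.path(dir, "exposure.tsv"))
  write_summary_table(outcome, file.path(dir, "outcome.tsv"))
  jsonlite::write_json(
    list(beta_causal = ds$truth$beta_causal, gamma = ds$truth$gamma,
         alpha = ds$truth$alpha, valid = ds$truth$valid,
         proxy_id = inst$proxy_id, proxy_r2 = inst$proxy_r2),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE,
    na = "null", pretty = TRUE)
  invisible(dir)
}

#' Read a simulated dataset back from disk
#'
#' Inverse of [write_dataset()]: reads the two summary tables through the
#' regular reader, re-harmonizes them, and reattaches proxy provenance and
#' ground truth from `truth.json`.
#'
#' @param dir Directory written by [write_dataset()].
#' @return A list of class `"mr_simulation"` (without the generating
#'   config).
#' @export
read_dataset <- function(dir) {
  exposure <- read_summary_table(file.path(dir, "exposure.tsv"))
  outcome <- read_summary_table(file.path(dir, "outcome.tsv"))
  inst <- harmonize_pair(exposure, outcome, mode = "pre_oriented")
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  inst$proxy_id <- as.character(truth$proxy_id)
  inst$proxy_r2 <- truth$proxy_r2
  inst$outcome_source <- "simulated"
  inst <- attach_af_band_flag(inst)
  structure(list(instruments = inst,
                 truth = list(beta_causal = truth$beta_causal,
                              gamma = truth$gamma, alpha = truth$alpha,
                              valid = truth$valid)),
            class = "mr_simulation")
}
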