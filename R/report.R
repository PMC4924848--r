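#' Scatter-plot data: per-SNP effects with fitted MR lines
#'
#' The classic two-sample MR display: each SNP's exposure effect against its
#' outcome effect, with the IVW fit (a line through the origin with slope
#' equal to the pooled estimate) and the MR-Egger fit (free intercept)
#' overlaid. Points are re-oriented to non-negative exposure effects, the
#' orientation both fits use.
#'
#' @param instruments Harmonized instrument tibble.
#' @param ivw One-row IVW result from [mr_ivw()]; computed if `NULL`.
#' @param egger Two-row Egger result from [mr_egger()]; computed if `NULL`.
#' @return A list of class `"mr_scatter"`: `points` (tibble `snp_id`,
#'   `beta_exposure`, `beta_outcome`, `se_outcome`) and `lines` (tibble
#'   `method`, `intercept`, `slope`).
#' @export
scatter_data <- function(instruments, ivw = NULL, egger = NULL) {
  if (is.null(ivw)) ivw <- mr_ivw(instruments)
  if (is.null(egger)) egger <- mr_egger(instruments)
  flip <- sign(instruments$beta_exposure)
  flip[flip == 0] <- 1
  points <- tibble::tibble(
    snp_id = instruments$snp_id,
    beta_exposure = instruments$beta_exposure * flip,
    beta_outcome = instruments$beta_outcome * flip,
    se_outcome = instruments$se_outcome)
  lines <- tibble::tibble(
    method = c("IVW_fixed", "Egger"),
    intercept = c(0, egger$beta[egger$method == "Egger_intercept"]),
    slope = c(ivw$beta, egger$beta[egger$method == "Egger_slope"]))
  structure(list(points = points, lines = lines), class = "mr_scatter")
}

#' Funnel-plot data: per-SNP estimates against precision
#'
#' The meta-analysis funnel adapted to MR: each SNP's Wald ratio against its
#' precision (`1/se_ratio`). Under no directional pleiotropy the cloud is
#' symmetric about the pooled estimate; low-precision estimates drifting to
#' one side suggest small-instrument bias from directional pleiotropy.
#'
#' The `exposure_beta_over_se` column is an experimental alternative
#' abscissa — the exposure association scaled by its standard error, a
#' frequency-sensitive precision measure (low-frequency alleles are measured
#' with larger SEs); it is `NA` when exposure SEs are unavailable.
#'
#' @param instruments Harmonized instrument tibble.
#' @param ratios Ratio table from [wald_ratios()]; computed if `NULL`.
#' @return Tibble `snp_id`, `ratio`, `precision`, `exposure_beta_over_se`.
#' @export
funnel_data <- function(instruments, ratios = NULL) {
  if (is.null(ratios)) ratios <- wald_ratios(instruments)
  stopifnot(all(ratios$snp_id == instruments$snp_id))
  tibble::tibble(
    snp_id = ratios$snp_id,
    ratio = ratios$ratio,
    precision = 1 / ratios$se_ratio,
    exposure_beta_over_se = instruments$beta_exposure /
      instruments$se_exposure)
}

#' Forest-plot data from a suite result
#'
#' One row per analysis-by-method with the OR-scale estimate and CI, in the
#' order the suite was specified. Failed analyses are dropped.
#'
#' @param suite Result tibble from [run_suite()].
#' @return Tibble `analysis`, `method`, `or`, `ci_low`, `ci_high`, `n_snp`.
#' @export
forest_data <- function(suite) {
  ok <- suite[suite$status == "ok", ]
  tibble::tibble(analysis = ok$analysis, method = ok$method,
                 or = ok$or, ci_low = ok$or_ci_low, ci_high = ok$or_ci_high,
                 n_snp = ok$n_snp)
}

#' Run the full pipeline and write a results bundle
#'
#' Executes harmonization, flag attachment, the sensitivity suite, and the
#' plot-data exports, writing `results.tsv`, `results.json`, `scatter.tsv`,
#' `scatter_lines.tsv`, `funnel.tsv`, `forest.tsv`, and `run.log` (instrument
#' counts at each stage plus the echoed configuration) into `output_dir`.
#' Every plot-data file is a pure view of the stored results and can be
#' regenerated from `results.json` alone.
#'
#' Inputs are given either as the packaged BMI-MS instrument set
#' (`fixture = TRUE`) or as exposure/outcome summary-table paths with
#' column maps.
#'
#' @param output_dir Directory for the bundle (created if missing).
#' @param fixture If `TRUE`, analyse the packaged instrument set.
#' @param exposure_path,outcome_path Paths to summary tables (ignored when
#'   `fixture = TRUE`).
#' @param exposure_map,outcome_map Column maps for [read_summary_table()].
#' @param mode Harmonization mode, see [harmonize_pair()].
#' @param specs Sensitivity suite, default [default_specs()].
#' @param height_ld Optional [ld_table()] for the height-LD filter.
#' @param n_boot,seed Weighted-median bootstrap settings.
#' @return The suite result tibble, invisibly.
#' @export
run_pipeline <- function(output_dir, fixture = FALSE,
                         exposure_path = NULL, outcome_path = NULL,
                         exposure_map = NULL, outcome_map = NULL,
                         mode = "pre_oriented", specs = default_specs(),
                         height_ld = NULL, n_boot = 5000, seed = 42) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log_step <- function(...) {
    line <- paste0(...)
    message(line)
    log_lines <<- c(log_lines, line)
  }

  if (fixture) {
    log_step("input: packaged BMI-MS instrument set")
    instruments <- fixture_instruments()
  } else {
    if (is.null(exposure_path) || is.null(outcome_path)) {
      stop("run_pipeline: exposure_path and outcome_path are required ",
           "unless fixture = TRUE", call. = FALSE)
    }
    log_step("input: exposure=", exposure_path, " outcome=", outcome_path)
    exposure <- read_summary_table(exposure_path, exposure_map,
                                   trait = "exposure")
    outcome <- read_summary_table(outcome_path, outcome_map,
                                  trait = "outcome")
    shared <- intersect(exposure$snp_id, outcome$snp_id)
    log_step("shared SNPs: ", length(shared), " of ", nrow(exposure),
             " exposure / ", nrow(outcome), " outcome records")
    exposure <- exposure[match(shared, exposure$snp_id), ]
    outcome <- outcome[match(shared, outcome$snp_id), ]
    instruments <- harmonize_pair(exposure, outcome, mode = mode)
    instruments <- attach_af_band_flag(instruments)
  }
  log_step("harmonized instruments: ", nrow(instruments), " (",
           sum(!is.na(instruments$proxy_id)), " proxies)")

  suite <- withCallingHandlers(
    run_suite(instruments, specs = specs, height_ld = height_ld,
              n_boot = n_boot, seed = seed),
    message = function(m) {
      log_lines <<- c(log_lines, sub("\n$", "", conditionMessage(m)))
      invokeRestart("muffleMessage")
    })

  primary_name <- specs[[1]]$name
  ivw <- mr_ivw(instruments)
  egger <- mr_egger(instruments)
  sc <- scatter_data(instruments, ivw = ivw, egger = egger)
  fu <- funnel_data(instruments)
  fo <- forest_data(suite)

  readr::write_tsv(suite, file.path(output_dir, "results.tsv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(config = list(fixture = fixture, mode = mode, n_boot = n_boot,
                       seed = seed, primary = primary_name),
         results = suite,
         ratios = wald_ratios(instruments),
         instruments = instruments),
    file.path(output_dir, "results.json"),
    digits = NA, auto_unbox = TRUE, na = "null", pretty = TRUE)
  readr::write_tsv(sc$points, file.path(output_dir, "scatter.tsv"),
                   progress = FALSE)
  readr::write_tsv(sc$lines, file.path(output_dir, "scatter_lines.tsv"),
                   progress = FALSE)
  readr::write_tsv(fu, file.path(output_dir, "funnel.tsv"), progress = FALSE)
  readr::write_tsv(fo, file.path(output_dir, "forest.tsv"), progress = FALSE)
  log_step("bundle written to ", output_dir)
  writeLines(c(log_lines,
               paste0("config: fixture=", fixture, " mode=", mode,
                      " n_boot=", n_boot, " seed=", seed)),
             file.path(output_dir, "run.log"))
  invisible(suite)
}

need_ggplot2 <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot rendering requires the ggplot2 package", call. = FALSE)
  }
}

#' Render the scatter, funnel, and forest displays
#'
#' Thin ggplot2 layers over the corresponding plot-data tables; all
#' quantitative content lives in the tables.
#'
#' @param x Output of [scatter_data()], [funnel_data()], or [forest_data()].
#' @return A ggplot object.
#' @export
mr_scatter_plot <- function(x) {
  need_ggplot2()
  stopifnot(inherits(x, "mr_scatter"))
  ggplot2::ggplot(x$points,
                  ggplot2::aes(.data$beta_exposure, .data$beta_outcome)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$beta_outcome - .data$se_outcome,
      ymax = .data$beta_outcome + .data$se_outcome),
      size = 0.2, colour = "grey40") +
    ggplot2::geom_abline(data = x$lines, ggplot2::aes(
      intercept = .data$intercept, slope = .data$slope,
      colour = .data$method)) +
    ggplot2::labs(x = "Effect on exposure (SD/allele)",
                  y = "Effect on outcome (log-odds/allele)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname mr_scatter_plot
#' @export
mr_funnel_plot <- function(x) {
  need_ggplot2()
  ggplot2::ggplot(x, ggplot2::aes(.data$ratio, .data$precision)) +
    ggplot2::geom_point(colour = "grey40") +
    ggplot2::labs(x = "Per-SNP causal estimate (log-odds/SD)",
                  y = "Precision (1/SE)") +
    ggplot2::theme_minimal()
}

#' @rdname mr_scatter_plot
#' @export
mr_forest_plot <- function(x) {
  need_ggplot2()
  x$label <- paste(x$analysis, x$method, sep = " / ")
  x$label <- factor(x$label, levels = rev(unique(x$label)))
  ggplot2::ggplot(x, ggplot2::aes(.data$or, .data$label)) +
    ggplot2::geom_vline(xintercept = 1, colour = "grey70") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "OR per SD exposure", y = NULL) +
    ggplot2::theme_minimal()
}
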