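#' Declare one sensitivity analysis
#'
#' A named, ordered list of instrument filters plus the estimators to run on
#' the surviving set. Available filters:
#'
#' * `"drop_proxies"` — keep only directly genotyped instruments
#'   (`proxy_id` missing);
#' * `"drop_af_band_proxies"` — remove instruments carrying the
#'   allele-frequency-band flag (proxies with EAF in the ambiguous band,
#'   see [attach_af_band_flag()]);
#' * `"drop_height_ld"` — remove instruments in LD (r-squared > 0.05) with
#'   any locus in a supplied height-associated list;
#' * `"restrict_source:<label>"` — keep instruments whose outcome study
#'   matches `<label>`.
#'
#' @param name Unique label for the analysis.
#' @param filters Character vector drawn from the set above, applied in
#'   order.
#' @param estimators Subset of `c("IVW_fixed", "Egger", "WeightedMedian")`.
#' @return An object of class `"analysis_spec"`.
#' @export
analysis_spec <- function(name, filters = character(),
                          estimators = c("IVW_fixed", "Egger",
                                         "WeightedMedian")) {
  known <- c("drop_proxies", "drop_af_band_proxies", "drop_height_ld")
  ok <- filters %in% known | grepl("^restrict_source:.+$", filters)
  if (any(!ok)) {
    stop("unknown filter(s): ", paste(filters[!ok], collapse = ", "),
         call. = FALSE)
  }
  estimators <- match.arg(estimators, several.ok = TRUE)
  structure(list(name = name, filters = filters, estimators = estimators),
            class = "analysis_spec")
}

#' @export
print.analysis_spec <- function(x, ...) {
  cat("analysis spec '", x$name, "': filters [",
      paste(x$filters, collapse = ", "), "], estimators [",
      paste(x$estimators, collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' The default sensitivity suite
#'
#' Primary analysis on all instruments, proxies with ambiguous allele
#' frequency excluded, and all proxies excluded — the standard battery for
#' checking that proxy substitution did not distort the pooled estimate.
#'
#' @return List of [analysis_spec()] objects.
#' @export
default_specs <- function() {
  list(
    analysis_spec("All SNPs"),
    analysis_spec("AF-band proxies excluded", "drop_af_band_proxies"),
    analysis_spec("All proxies excluded", "drop_proxies"))
}

#' Apply sensitivity filters to an instrument set
#'
#' Filters compose in the listed order (for the default suite they touch
#' disjoint attributes, so the order does not matter).
#'
#' @param instruments Harmonized instrument tibble.
#' @param filters Character vector as in [analysis_spec()].
#' @param height_ld An [ld_table()] of r-squared between instrument SNPs and
#'   height-associated loci; required by `"drop_height_ld"`. Pairs absent
#'   from the table are treated as not in LD.
#' @param r2_max LD threshold for the height filter, default 0.05.
#' @return The filtered instrument tibble.
#' @export
apply_filters <- function(instruments, filters, height_ld = NULL,
                          r2_max = 0.05) {
  for (f in filters) {
    if (f == "drop_proxies") {
      instruments <- instruments[is.na(instruments$proxy_id), ]
    } else if (f == "drop_af_band_proxies") {
      instruments <- instruments[!instruments$flag_af_band, ]
    } else if (f == "drop_height_ld") {
      if (is.null(height_ld)) {
        stop("drop_height_ld requires a height_ld LD table", call. = FALSE)
      }
      instruments <- instruments[!in_ld_with_any(instruments$snp_id,
                                                 height_ld, r2_max), ]
    } else if (grepl("^restrict_source:", f)) {
      src <- sub("^restrict_source:", "", f)
      instruments <- instruments[!is.na(instruments$outcome_source) &
                                   instruments$outcome_source == src, ]
    } else {
      stop("unknown filter: ", f, call. = FALSE)
    }
  }
  instruments
}

# TRUE for each id having measured r2 > r2_max with any locus in the table.
in_ld_with_any <- function(ids, ld, r2_max) {
  parts <- strsplit(names(ld$r2), "\r", fixed = TRUE)
  loci <- unique(c(vapply(parts, `[`, "", 1), vapply(parts, `[`, "", 2)))
  vapply(ids, function(id) {
    others <- setdiff(loci, id)
    if (length(others) == 0) return(FALSE)
    r2 <- ld_r2(ld, rep(id, length(others)), others)
    any(!is.na(r2) & r2 > r2_max)
  }, logical(1), USE.NAMES = FALSE)
}

#' Run a suite of sensitivity analyses
#'
#' Applies each spec's filters and runs its estimators, returning one row
#' per analysis-by-method. A spec that filters the set below 3 instruments
#' is marked failed (with a reason) and the run continues.
#'
#' @param instruments Harmonized instrument tibble.
#' @param specs List of [analysis_spec()]s, default [default_specs()].
#' @inheritParams apply_filters
#' @param n_boot,seed Weighted-median bootstrap settings.
#' @return Tibble with columns `analysis`, `n_snp`, `n_proxy`, `status`,
#'   `reason`, and the MR-result columns.
#' @examples
#' run_suite(fixture_instruments(), n_boot = 200)
#' @export
run_suite <- function(instruments, specs = default_specs(),
                      height_ld = NULL, n_boot = 5000, seed = 42) {
  stopifnot(length(specs) >= 1)
  names <- vapply(specs, function(s) s$name, "")
  if (anyDuplicated(names)) {
    stop("duplicate analysis names in suite: ",
         paste(unique(names[duplicated(names)]), collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(specs, function(spec) {
    kept <- apply_filters(instruments, spec$filters, height_ld = height_ld)
    n_proxy <- sum(!is.na(kept$proxy_id))
    message("analysis '", spec$name, "': ", nrow(instruments), " -> ",
            nrow(kept), " instruments (", n_proxy, " proxies)")
    base <- tibble::tibble(analysis = spec$name, n_snp = nrow(kept),
                           n_proxy = n_proxy)
    if (nrow(kept) < 3) {
      return(dplyr::mutate(base, status = "failed",
                           reason = "fewer than 3 instruments after filters"))
    }
    res <- mr_all(kept, methods = spec$estimators, n_boot = n_boot,
                  seed = seed)
    dplyr::bind_cols(
      base[rep(1, nrow(res)), ],
      tibble::tibble(status = "ok", reason = NA_character_),
      res[setdiff(names(res), "n_snp")])
  })
  dplyr::bind_rows(rows)
}

#' Swap exposure and outcome roles of an instrument set
#'
#' Helper for bidirectional analyses: returns the same instruments with
#' exposure and outcome effects (and SEs) interchanged. Applying it twice is
#' the identity.
#'
#' @param instruments Harmonized instrument tibble.
#' @return Instrument tibble with roles swapped.
#' @export
swap_roles <- function(instruments) {
  out <- instruments
  out$beta_exposure <- instruments$beta_outcome
  out$se_exposure <- instruments$se_outcome
  out$beta_outcome <- instruments$beta_exposure
  out$se_outcome <- instruments$se_exposure
  out
}

#' Bidirectional (reverse-direction) MR analysis
#'
#' Runs the identical estimator stack on an instrument set in which the
#' original outcome plays the exposure role (e.g. MS liability as exposure,
#' BMI as outcome), to test for reverse causation. The result rows carry a
#' `direction` label; effect units are SD of the (new) outcome per log-odds
#' of the (new) exposure, so OR-scale columns are dropped.
#'
#' @param instruments Harmonized instruments already oriented with the
#'   reverse-direction exposure (see [swap_roles()]).
#' @inheritParams mr_all
#' @param direction Label stored on the results, default `"reverse"`.
#' @return MR-result tibble with a leading `direction` column and no
#'   OR-scale columns.
#' @export
run_bidirectional <- function(instruments,
                              methods = c("IVW_fixed", "Egger",
                                          "WeightedMedian"),
                              n_boot = 5000, seed = 42,
                              direction = "reverse") {
  res <- mr_all(instruments, methods = methods, n_boot = n_boot, seed = seed)
  res <- res[setdiff(names(res), c("or", "or_ci_low", "or_ci_high"))]
  dplyr::bind_cols(tibble::tibble(direction = rep(direction, nrow(res))),
                   res)
}
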