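#' Two-sided normal p-value from a z-score
#'
#' `2 * (1 - pnorm(|z|))`, floored at the smallest positive normal double so
#' downstream logs and serializations never see an exact zero.
#'
#' @param z Finite z-score(s).
#' @return p-value(s) in `(0, 1]`.
#' @export
p_two_sided <- function(z) {
  if (any(!is.finite(z))) stop("p_two_sided: non-finite z", call. = FALSE)
  pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
}

#' Per-SNP Wald ratio estimates
#'
#' The instrumental-variable estimate contributed by a single SNP: the
#' outcome effect divided by the exposure effect. The standard error is the
#' first-order delta-method approximation `se_outcome / |beta_exposure|`,
#' which ignores exposure-side uncertainty (the no-measurement-error, NOME,
#' assumption standard in two-sample MR with strong instruments).
#'
#' @param instruments Harmonized instrument tibble (see [harmonize_pair()]).
#' @return Tibble with columns `snp_id`, `ratio`, `se_ratio`,
#'   `weight` (`1/se_ratio^2`).
#' @export
wald_ratios <- function(instruments) {
  zero <- instruments$beta_exposure == 0
  if (any(zero)) {
    stop("zero exposure effect; Wald ratio undefined for: ",
         paste(instruments$snp_id[zero], collapse = ", "), call. = FALSE)
  }
  se_ratio <- instruments$se_outcome / abs(instruments$beta_exposure)
  tibble::tibble(
    snp_id = instruments$snp_id,
    ratio = instruments$beta_outcome / instruments$beta_exposure,
    se_ratio = se_ratio,
    weight = 1 / se_ratio^2)
}

# Accept either a ratio table or an instrument table.
as_ratios <- function(x) {
  if ("ratio" %in% names(x)) x else wald_ratios(x)
}

mr_result_row <- function(method, beta, se, n_snp, het = NULL) {
  z <- z975()
  # degenerate SEs (exact fits, single-replicate bootstraps) must not
  # poison the row
  pvalue <- if (is.na(se)) {
    NA_real_
  } else if (se == 0) {
    if (beta == 0) 1 else .Machine$double.xmin
  } else {
    p_two_sided(beta / se)
  }
  tibble::tibble(
    method = method,
    beta = beta,
    se = se,
    ci_low = beta - z * se,
    ci_high = beta + z * se,
    pvalue = pvalue,
    or = exp(beta),
    or_ci_low = exp(beta - z * se),
    or_ci_high = exp(beta + z * se),
    n_snp = n_snp,
    Q = if (is.null(het)) NA_real_ else het$Q,
    Q_df = if (is.null(het)) NA_integer_ else het$df,
    i2 = if (is.null(het)) NA_real_ else het$i2,
    i2_ci_low = if (is.null(het)) NA_real_ else het$i2_ci_low,
    i2_ci_high = if (is.null(het)) NA_real_ else het$i2_ci_high)
}

#' Fixed-effects inverse-variance-weighted causal estimate
#'
#' Pools per-SNP Wald ratios with weights `1/se_ratio^2` under a
#' fixed-effects meta-analytic model: `beta = sum(w * ratio) / sum(w)`,
#' `se = 1/sqrt(sum(w))`. A heterogeneity block (Cochran's Q, I-squared with
#' test-based CI) is attached when at least two ratios are supplied.
#'
#' The estimate is algebraically identical to the slope of a zero-intercept
#' weighted regression of outcome effects on exposure effects with weights
#' `1/se_outcome^2`.
#'
#' @param x A ratio table from [wald_ratios()] or a harmonized instrument
#'   tibble.
#' @return A one-row MR-result tibble: `method`, `beta`, `se`, `ci_low`,
#'   `ci_high`, `pvalue`, OR-scale columns, `n_snp`, and the heterogeneity
#'   block (`Q`, `Q_df`, `i2`, `i2_ci_low`, `i2_ci_high`).
#' @examples
#' mr_ivw(fixture_instruments())
#' @export
mr_ivw <- function(x) {
  r <- as_ratios(x)
  if (nrow(r) < 1) stop("mr_ivw: no ratio estimates", call. = FALSE)
  w <- r$weight
  beta <- sum(w * r$ratio) / sum(w)
  se <- 1 / sqrt(sum(w))
  het <- if (nrow(r) >= 2) heterogeneity(r, beta) else NULL
  mr_result_row("IVW_fixed", beta, se, nrow(r), het)
}

#' Cochran's Q and I-squared around a pooled estimate
#'
#' `Q = sum(w * (ratio - beta_pooled)^2)` with `df = k - 1`, and
#' `I2 = max(0, 100 * (Q - df) / Q)`. The I-squared confidence interval uses
#' the test-based method on `ln H` (`H^2 = Q/df`) with back-transformation,
#' truncated to `[0, 100]`; it requires `k >= 3`.
#'
#' @param x Ratio table or instrument tibble with at least 2 rows.
#' @param beta_pooled Pooled estimate; defaults to the fixed-effects IVW
#'   value computed from `x`.
#' @return A one-row tibble: `Q`, `df`, `i2`, `i2_ci_low`, `i2_ci_high`.
#' @export
heterogeneity <- function(x, beta_pooled = NULL) {
  r <- as_ratios(x)
  k <- nrow(r)
  if (k < 2) stop("heterogeneity requires at least 2 estimates",
                  call. = FALSE)
  w <- r$weight
  if (is.null(beta_pooled)) beta_pooled <- sum(w * r$ratio) / sum(w)
  Q <- sum(w * (r$ratio - beta_pooled)^2)
  df <- k - 1L
  i2 <- if (Q > 0) max(0, 100 * (Q - df) / Q) else 0

  if (k >= 3) {
    # test-based CI for ln H (H = sqrt(Q/df)), Higgins-Thompson style
    se_ln_h <- if (Q > k) {
      0.5 * (log(Q) - log(df)) / (sqrt(2 * Q) - sqrt(2 * k - 3))
    } else {
      sqrt(1 / (2 * (k - 2)) * (1 - 1 / (3 * (k - 2)^2)))
    }
    ln_h <- 0.5 * (log(max(Q, .Machine$double.xmin)) - log(df))
    ln_h <- max(ln_h, 0)
    z <- z975()
    h_lo <- exp(ln_h - z * se_ln_h)
    h_hi <- exp(ln_h + z * se_ln_h)
    i2_from_h <- function(h) max(0, min(100, 100 * (h^2 - 1) / h^2))
    i2_lo <- i2_from_h(h_lo)
    i2_hi <- i2_from_h(h_hi)
  } else {
    i2_lo <- NA_real_
    i2_hi <- NA_real_
  }
  tibble::tibble(Q = Q, df = df, i2 = i2,
                 i2_ci_low = i2_lo, i2_ci_high = i2_hi)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with a
#' free intercept, weights `1/se_outcome^2`. A nonzero intercept is evidence
#' of directional pleiotropy; the slope is a pleiotropy-adjusted causal
#' estimate (consistent under the InSIDE condition: instrument strength
#' independent of direct effects). Instruments are first re-oriented so
#' every exposure effect is non-negative — the regression is not invariant
#' to per-SNP sign flips, so a consistent orientation is required.
#'
#' @param instruments Harmonized instrument tibble, at least 3 rows.
#' @return A two-row MR-result tibble, methods `"Egger_intercept"` (log-odds
#'   units) and `"Egger_slope"` (per SD exposure).
#' @examples
#' mr_egger(fixture_instruments())
#' @export
mr_egger <- function(instruments) {
  if (nrow(instruments) < 3) {
    stop("MR-Egger requires at least 3 instruments", call. = FALSE)
  }
  flip <- sign(instruments$beta_exposure)
  flip[flip == 0] <- 1
  g <- instruments$beta_exposure * flip
  G <- instruments$beta_outcome * flip
  if (stats::sd(g) == 0) {
    stop("MR-Egger: no spread in exposure effects (singular design)",
         call. = FALSE)
  }
  w <- 1 / instruments$se_outcome^2
  fit <- stats::lm(G ~ g, weights = w)
  co <- summary(fit)$coefficients
  # normal-theory (z) inference on the WLS coefficients
  rbind(
    mr_result_row("Egger_intercept", co[1, 1], co[1, 2], nrow(instruments)),
    mr_result_row("Egger_slope", co[2, 1], co[2, 2], nrow(instruments)))
}

#' Weighted median of a set of estimates
#'
#' Order the estimates, normalize the weights to sum to one, form the
#' cumulative midpoint positions `S_j - w_j/2`, and linearly interpolate the
#' estimate at position one half. With equal weights and odd `k` this is the
#' plain sample median.
#'
#' @param b Numeric estimates.
#' @param w Positive weights.
#' @return The weighted median.
#' @export
weighted_median_point <- function(b, w) {
  stopifnot(length(b) == length(w), all(w > 0))
  o <- order(b)
  b <- b[o]
  w <- w[o] / sum(w)
  mid <- cumsum(w) - w / 2
  if (0.5 <= mid[1]) return(b[1])
  if (0.5 >= mid[length(mid)]) return(b[length(b)])
  stats::approx(mid, b, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' The weighted median of the per-SNP Wald ratios with inverse-variance
#' weights. It is a consistent estimate of the causal effect as long as more
#' than half of the total weight comes from valid (non-pleiotropic)
#' instruments, making it robust where IVW is not. The standard error comes
#' from a parametric bootstrap: exposure and outcome effects are resampled
#' from normal distributions centred on their estimates with their standard
#' errors, the ratios, weights and weighted median are recomputed each
#' replicate, and the SE is the standard deviation over replicates
#' (seed-deterministic).
#'
#' @param instruments Harmonized instrument tibble, at least 3 rows.
#'   Missing exposure SEs are treated as zero in the bootstrap.
#' @param n_boot Number of bootstrap replicates, default 5000.
#' @param seed RNG seed for the bootstrap, default 42.
#' @return A one-row MR-result tibble, method `"WeightedMedian"`.
#' @examples
#' mr_weighted_median(fixture_instruments(), n_boot = 200, seed = 1)
#' @export
mr_weighted_median <- function(instruments, n_boot = 5000, seed = 42) {
  if (nrow(instruments) < 3) {
    stop("weighted median requires at least 3 instruments", call. = FALSE)
  }
  if (n_boot < 1) stop("n_boot must be at least 1", call. = FALSE)
  r <- wald_ratios(instruments)
  point <- weighted_median_point(r$ratio, r$weight)

  k <- nrow(instruments)
  se_exp <- instruments$se_exposure
  se_exp[is.na(se_exp)] <- 0
  boot <- local_seed(seed, {
    g_star <- matrix(stats::rnorm(k * n_boot, instruments$beta_exposure,
                                  se_exp), nrow = k)
    G_star <- matrix(stats::rnorm(k * n_boot, instruments$beta_outcome,
                                  instruments$se_outcome), nrow = k)
    vapply(seq_len(n_boot), function(i) {
      ratio <- G_star[, i] / g_star[, i]
      w <- (g_star[, i] / instruments$se_outcome)^2
      weighted_median_point(ratio, w)
    }, numeric(1))
  })
  mr_result_row("WeightedMedian", point, stats::sd(boot), k)
}

# Evaluate expr under a temporary RNG state; the caller's stream resumes
# unchanged afterwards.
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Run the full estimator stack on one instrument set
#'
#' Convenience wrapper producing the fixed-effects IVW estimate, the
#' MR-Egger intercept and slope, and the weighted median as one result
#' table.
#'
#' @inheritParams mr_weighted_median
#' @param methods Subset of `c("IVW_fixed", "Egger", "WeightedMedian")`.
#' @return MR-result tibble, one row per estimate.
#' @export
mr_all <- function(instruments,
                   methods = c("IVW_fixed", "Egger", "WeightedMedian"),
                   n_boot = 5000, seed = 42) {
  methods <- match.arg(methods, several.ok = TRUE)
  out <- list()
  if ("IVW_fixed" %in% methods) out <- c(out, list(mr_ivw(instruments)))
  if ("Egger" %in% methods) out <- c(out, list(mr_egger(instruments)))
  if ("WeightedMedian" %in% methods) {
    out <- c(out, list(mr_weighted_median(instruments, n_boot = n_boot,
                                          seed = seed)))
  }
  dplyr::bind_rows(out)
}
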