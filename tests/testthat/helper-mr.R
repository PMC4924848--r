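# Shared builders for small instrument sets and independent oracles.

make_instruments <- function(beta_exposure, beta_outcome, se_outcome,
                             se_exposure = rep(0.003,
                                               length(beta_exposure)),
                             snp_id = sprintf("rs%03d",
                                              seq_along(beta_exposure)),
                             proxy_id = rep(NA_character_,
                                            length(beta_exposure)),
                             proxy_r2 = rep(1, length(beta_exposure)),
                             eaf = rep(0.3, length(beta_exposure))) {
  tibble::tibble(
    snp_id = snp_id, effect_allele = "A",
    beta_exposure = beta_exposure, se_exposure = se_exposure,
    beta_outcome = beta_outcome, se_outcome = se_outcome,
    eaf = eaf, outcome_source = "test",
    proxy_id = proxy_id, proxy_r2 = proxy_r2,
    flag_palindromic = FALSE, flag_af_band = FALSE, flag_height_ld = FALSE)
}

random_instruments <- function(k, seed) {
  set.seed(seed)
  make_instruments(
    beta_exposure = runif(k, 0.01, 0.08),
    beta_outcome = rnorm(k, 0.02, 0.03),
    se_outcome = runif(k, 0.01, 0.05),
    se_exposure = runif(k, 0.002, 0.006))
}

# one fixture load per test run
cached_fixture_instruments <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressMessages(fixture_instruments())
    }
    cache
  }
})

# Independent WLS via explicit normal equations (X'WX)^-1 X'Wy, with
# coefficient covariance scaled by the weighted residual mean square.
wls_oracle <- function(x, y, w, intercept = TRUE) {
  X <- if (intercept) cbind(1, x) else cbind(x)
  W <- diag(w)
  xtwx <- t(X) %*% W %*% X
  coef <- solve(xtwx, t(X) %*% W %*% y)
  resid <- y - X %*% coef
  sigma2 <- sum(w * resid^2) / (length(y) - ncol(X))
  se <- sqrt(diag(solve(xtwx)) * sigma2)
  list(coef = as.numeric(coef), se = as.numeric(se))
}

# Weighted median by minimizing the weighted L1 loss on a fine grid.
weighted_median_grid_oracle <- function(b, w, step = 1e-5) {
  grid <- seq(min(b), max(b), by = step)
  loss <- vapply(grid, function(x) sum(w * abs(x - b)), numeric(1))
  grid[which.min(loss)]
}

# The LD retention rule applied by independent elimination: repeatedly take
# the smallest-p remaining SNP, retain it, and discard every remaining SNP
# measured in LD with it above the threshold.
ld_prune_oracle <- function(snps, ld, r2_max = 0.05) {
  remaining <- snps[order(snps$pvalue, snps$snp_id), ]
  kept <- character(0)
  while (nrow(remaining) > 0) {
    top <- remaining$snp_id[1]
    kept <- c(kept, top)
    remaining <- remaining[-1, , drop = FALSE]
    if (nrow(remaining) > 0) {
      r2 <- ld_r2(ld, rep(top, nrow(remaining)), remaining$snp_id)
      remaining <- remaining[is.na(r2) | r2 <= r2_max, , drop = FALSE]
    }
  }
  kept
}

random_ld_table <- function(ids, density, seed) {
  set.seed(seed)
  pairs <- t(combn(ids, 2))
  keep <- runif(nrow(pairs)) < density
  ld_table(pairs[keep, 1], pairs[keep, 2],
           runif(sum(keep), 0, 1))
}
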