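test_that("Wald ratios divide outcome by exposure with delta-method SEs", {
  inst <- make_instruments(beta_exposure = c(0.082, 0.03, 0.05),
                           beta_outcome = c(0, 0.03, 0.01),
                           se_outcome = c(0.018, 0.02, 0.01))
  r <- wald_ratios(inst)
  expect_equal(r$ratio, c(0, 1, 0.2))
  expect_equal(r$se_ratio[3], 0.2)
  expect_equal(r$weight, 1 / r$se_ratio^2)

  inst$beta_exposure[2] <- 0
  expect_error(wald_ratios(inst), "rs002")

  # negative exposure effect: ratio sign preserved, SE uses |beta|
  inst2 <- make_instruments(-0.05, 0.01, 0.01)
  r2 <- wald_ratios(inst2)
  expect_equal(r2$ratio, -0.2)
  expect_equal(r2$se_ratio, 0.2)
})

test_that("fixed-effects IVW pools by inverse variance", {
  one <- make_instruments(0.05, 0.02, 0.015)
  res <- mr_ivw(one)
  expect_equal(res$beta, 0.4)
  expect_equal(res$se, 0.3)
  expect_true(is.na(res$i2))

  # two identical estimates (beta, s) pool to (beta, s/sqrt(2))
  two <- make_instruments(c(0.05, 0.05), c(0.02, 0.02), c(0.015, 0.015))
  res2 <- mr_ivw(two)
  expect_equal(res2$beta, 0.4)
  expect_equal(res2$se, 0.3 / sqrt(2))
  expect_equal(res2$Q, 0)
  expect_equal(res2$i2, 0)

  # random 8-instrument set vs an explicit summation oracle
  inst <- random_instruments(8, seed = 3)
  r <- wald_ratios(inst)
  w <- 1 / (inst$se_outcome / abs(inst$beta_exposure))^2
  b_oracle <- sum(w * r$ratio) / sum(w)
  se_oracle <- sqrt(1 / sum(w))
  res3 <- mr_ivw(inst)
  expect_equal(res3$beta, b_oracle, tolerance = 1e-12)
  expect_equal(res3$se, se_oracle, tolerance = 1e-12)
  expect_equal(res3$ci_low, b_oracle - qnorm(0.975) * se_oracle)

  expect_error(mr_ivw(inst[0, ]), "no ratio")
})

test_that("IVW equals the zero-intercept WLS slope to 1e-10", {
  for (seed in c(5, 17, 29)) {
    inst <- random_instruments(12, seed = seed)
    slope <- wls_oracle(inst$beta_exposure, inst$beta_outcome,
                        1 / inst$se_outcome^2, intercept = FALSE)$coef
    expect_equal(mr_ivw(inst)$beta, slope, tolerance = 1e-10)
  }
})

test_that("IVW and Q agree with metafor's fixed-effects model", {
  skip_if_not_installed("metafor")
  inst <- cached_fixture_instruments()
  r <- wald_ratios(inst)
  fit <- metafor::rma(yi = r$ratio, sei = r$se_ratio, method = "FE")
  res <- mr_ivw(inst)
  expect_equal(res$beta, as.numeric(fit$beta), tolerance = 1e-10)
  expect_equal(res$se, fit$se, tolerance = 1e-10)
  expect_equal(res$Q, fit$QE, tolerance = 1e-10)
})

test_that("heterogeneity matches hand computation and handles no spread", {
  same <- make_instruments(rep(0.05, 3), rep(0.02, 3), rep(0.01, 3))
  het <- heterogeneity(same)
  expect_equal(het$Q, 0)
  expect_equal(het$i2, 0)

  # constructed 3-study set, Q by hand: ratios 0.1/0.5/0.9, weights 4/1/4
  inst <- make_instruments(rep(1, 3), c(0.1, 0.5, 0.9), c(0.5, 1, 0.5))
  w <- c(4, 1, 4)
  b <- sum(w * c(0.1, 0.5, 0.9)) / sum(w)
  q_hand <- sum(w * (c(0.1, 0.5, 0.9) - b)^2)
  expect_equal(heterogeneity(inst)$Q, q_hand, tolerance = 1e-12)

  expect_error(heterogeneity(same[1, ]), "at least 2")
})

test_that("Egger regression recovers an exact line and matches WLS oracle", {
  set.seed(2)
  g <- runif(10, 0.01, 0.08)
  inst <- make_instruments(g, 0.01 + 0.5 * g, rep(0.02, 10))
  res <- mr_egger(inst)
  expect_equal(res$beta[res$method == "Egger_intercept"], 0.01,
               tolerance = 1e-10)
  expect_equal(res$beta[res$method == "Egger_slope"], 0.5,
               tolerance = 1e-10)

  inst2 <- random_instruments(9, seed = 8)
  o <- wls_oracle(inst2$beta_exposure, inst2$beta_outcome,
                  1 / inst2$se_outcome^2)
  res2 <- mr_egger(inst2)
  expect_equal(res2$beta, o$coef, tolerance = 1e-10)
  expect_equal(res2$se, o$se, tolerance = 1e-10)

  expect_error(mr_egger(inst2[1:2, ]), "at least 3")
  flat <- make_instruments(rep(0.05, 4), rnorm(4), rep(0.02, 4))
  expect_error(mr_egger(flat), "singular")
})

test_that("weighted median interpolates cumulative weight midpoints", {
  expect_equal(weighted_median_point(c(0.1, 0.5, 0.9), rep(1, 3)), 0.5)
  expect_equal(weighted_median_point(c(0.9, 0.1, 0.5), rep(2, 3)), 0.5)

  # equal weights, odd k: plain sample median
  for (seed in 1:5) {
    set.seed(seed)
    b <- rnorm(2 * sample(2:6, 1) + 1)
    expect_equal(weighted_median_point(b, rep(1, length(b))), median(b))
  }

  # dominant-weight pairs, interpolated between cumulative midpoints:
  # mids at 5/11 and 21/22, so position 0.5 maps to 1/11
  expect_equal(weighted_median_point(c(0, 1), c(10, 1)), 1 / 11)
  expect_equal(weighted_median_point(c(0, 1), c(1, 10)), 10 / 11)

  # the weighted-L1 minimizer is the non-interpolated weighted median; the
  # interpolated estimate must coincide with it whenever the half-weight
  # point falls on a cumulative midpoint, and bracket it within one
  # inter-point gap otherwise
  for (seed in 1:5) {
    set.seed(seed + 40)
    b <- rnorm(7)
    w <- runif(7, 0.5, 3)
    wm <- weighted_median_point(b, w)
    l1 <- weighted_median_grid_oracle(b, w)
    gap <- max(diff(sort(b)))
    expect_lte(abs(wm - l1), gap + 1e-12)
  }
  for (seed in 1:5) {
    set.seed(seed + 60)
    b <- rnorm(7)
    expect_lt(abs(weighted_median_point(b, rep(1, 7)) -
                    weighted_median_grid_oracle(b, rep(1, 7))), 1e-4)
  }
})

test_that("weighted-median bootstrap is seed-deterministic", {
  inst <- random_instruments(10, seed = 21)
  a <- mr_weighted_median(inst, n_boot = 300, seed = 9)
  b <- mr_weighted_median(inst, n_boot = 300, seed = 9)
  expect_identical(a, b)
  c <- mr_weighted_median(inst, n_boot = 300, seed = 10)
  expect_false(identical(a$se, c$se))
  expect_equal(a$beta, c$beta)   # point estimate has no randomness
  expect_error(mr_weighted_median(inst, n_boot = 0), "n_boot")

  # the bootstrap must not disturb the caller's RNG stream
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  invisible(mr_weighted_median(inst, n_boot = 50, seed = 1))
  expect_identical(rnorm(1), before)
})

test_that("two-sided p-values match an erfc oracle and never hit zero", {
  expect_equal(p_two_sided(0), 1)
  expect_equal(p_two_sided(qnorm(0.975)), 0.05)
  expect_equal(p_two_sided(-qnorm(0.975)), 0.05)
  expect_equal(p_two_sided(4.2), pracma::erfc(4.2 / sqrt(2)),
               tolerance = 1e-12)
  expect_gt(p_two_sided(1000), 0)
  expect_error(p_two_sided(Inf), "non-finite")
})

test_that("estimators are invariant to reordering and joint sign flips", {
  inst <- random_instruments(15, seed = 31)
  set.seed(99)
  perm <- sample(15)
  flip <- sample(c(-1, 1), 15, replace = TRUE)
  mangled <- inst[perm, ]
  mangled$beta_exposure <- mangled$beta_exposure * flip[perm]
  mangled$beta_outcome <- mangled$beta_outcome * flip[perm]

  expect_equal(mr_ivw(mangled)$beta, mr_ivw(inst)$beta, tolerance = 1e-12)
  expect_equal(mr_ivw(mangled)$se, mr_ivw(inst)$se, tolerance = 1e-12)
  expect_equal(mr_egger(mangled)$beta, mr_egger(inst)$beta,
               tolerance = 1e-12)
  expect_equal(
    mr_weighted_median(mangled, n_boot = 50, seed = 1)$beta,
    mr_weighted_median(inst, n_boot = 50, seed = 1)$beta,
    tolerance = 1e-12)
})

test_that("Egger constrained to a zero intercept reproduces IVW", {
  inst <- random_instruments(11, seed = 44)
  fit <- lm(beta_outcome ~ 0 + beta_exposure, data = inst,
            weights = 1 / inst$se_outcome^2)
  expect_equal(unname(coef(fit)), mr_ivw(inst)$beta, tolerance = 1e-10)
})
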