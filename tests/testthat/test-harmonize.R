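test_that("odds ratios with CIs convert to log-odds and back", {
  conv <- or_to_log(1.00, 0.97, 1.04)
  expect_equal(conv$beta, 0)
  expect_equal(conv$se, 0.01778, tolerance = 1e-3)

  # constructed inverse: or = e with CI e * exp(-+z * 0.1)
  z <- qnorm(0.975)
  conv <- or_to_log(exp(1), exp(1 - z * 0.1), exp(1 + z * 0.1))
  expect_equal(conv$beta, 1)
  expect_equal(conv$se, 0.1)

  expect_error(or_to_log(1, 1, 1), "degenerate")
  expect_error(or_to_log(-1, 0.5, 2), "positive")
  expect_error(or_to_log(2, 0.5, 1.5), "bracket")

  # round trip to 1e-12 over random inputs
  set.seed(7)
  beta <- rnorm(50)
  se <- runif(50, 0.01, 0.5)
  ors <- log_to_or(beta, se)
  back <- or_to_log(ors$or, ors$ci_low, ors$ci_high)
  expect_equal(back$beta, beta, tolerance = 1e-12)
  expect_equal(back$se, se, tolerance = 1e-12)
})

test_that("allele-mode harmonization flips, flags, and fails correctly", {
  exposure <- tibble::tibble(
    snp_id = c("rs1", "rs2", "rs3"), chrom = "1",
    effect_allele = c("A", "A", "A"), other_allele = c("G", "T", "G"),
    eaf = c(0.3, 0.42, 0.2), beta = c(0.05, 0.04, 0.03),
    or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    se = c(0.01, 0.01, 0.01), pvalue = 1e-9, trait = "X", source = "S")
  outcome <- tibble::tibble(
    snp_id = c("rs1", "rs2", "rs3"), chrom = "1",
    effect_allele = c("G", "A", "C"), other_allele = c("A", "T", "G"),
    eaf = c(0.7, 0.42, 0.5), beta = c(0.02, 0.01, 0.01),
    or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    se = c(0.01, 0.01, 0.01), pvalue = 0.1, trait = "Y", source = "S")

  expect_error(harmonize_pair(exposure, outcome, mode = "alleles"), "rs3")

  inst <- harmonize_pair(exposure[1:2, ], outcome[1:2, ], mode = "alleles")
  # rs1: outcome effect allele is the exposure's other allele -> negated
  expect_equal(inst$beta_outcome[1], -0.02)
  expect_equal(inst$beta_exposure[1], 0.05)
  # rs2: palindromic A/T with AF in [0.4, 0.6] -> flagged, not dropped
  expect_true(inst$flag_palindromic[2])
  expect_false(inst$flag_palindromic[1])
  expect_equal(inst$beta_outcome[2], 0.01)

  # same orientation reported on the opposite strand: A/G vs T/C
  exposure2 <- exposure[1, ]           # effect A, other G
  outcome2 <- outcome[1, ]
  outcome2$effect_allele <- "T"
  outcome2$other_allele <- "C"
  inst2 <- harmonize_pair(exposure2, outcome2, mode = "alleles")
  expect_equal(inst2$beta_outcome, 0.02)
})

test_that("harmonization is involutive under outcome allele flips", {
  exposure <- tibble::tibble(
    snp_id = "rs9", chrom = "2", effect_allele = "A", other_allele = "G",
    eaf = 0.25, beta = 0.06, or = NA_real_, ci_low = NA_real_,
    ci_high = NA_real_, se = 0.01, pvalue = 1e-10, trait = "X",
    source = "S")
  outcome <- exposure
  outcome$beta <- 0.03
  outcome$pvalue <- 0.2
  flipped <- outcome
  flipped$effect_allele <- "G"
  flipped$other_allele <- "A"
  flipped$beta <- -outcome$beta
  flipped$eaf <- 1 - outcome$eaf
  a <- harmonize_pair(exposure, outcome, mode = "alleles")
  b <- harmonize_pair(exposure, flipped, mode = "alleles")
  expect_equal(a, b)
})

test_that("pre-oriented mode reproduces the published record layout", {
  fx <- suppressMessages(load_bmi_ms_fixture())
  inst <- suppressMessages(fixture_instruments(fx))
  i <- which(inst$snp_id == "rs1558902")
  expect_equal(inst$beta_exposure[i], 0.082)
  expect_equal(inst$beta_outcome[i], 0)
  expect_equal(inst$se_outcome[i], 0.01778, tolerance = 1e-3)
  expect_equal(sum(!is.na(inst$proxy_id)), 36)
  expect_equal(sum(inst$flag_af_band), 7)
})

test_that("the allele-frequency band flags only proxies, closed interval", {
  inst <- make_instruments(
    beta_exposure = rep(0.05, 5), beta_outcome = rep(0.01, 5),
    se_outcome = rep(0.02, 5),
    proxy_id = c("p1", NA, "p3", "p4", "p5"),
    proxy_r2 = c(0.9, 1, 0.9, 0.9, 0.9),
    eaf = c(0.42, 0.42, 0.39, 0.4, 0.6))
  inst <- attach_af_band_flag(inst)
  expect_equal(inst$flag_af_band, c(TRUE, FALSE, FALSE, TRUE, TRUE))

  inst$eaf[1] <- NA
  expect_warning(attach_af_band_flag(inst), "rs001")
  expect_false(suppressWarnings(attach_af_band_flag(inst))$flag_af_band[1])
})

test_that("dosage r-squared matches a covariance-formula oracle", {
  x <- c(0, 1, 2, 1, 0)
  expect_equal(r2_from_dosages(x, x), 1)
  expect_equal(r2_from_dosages(x, 2 - x), 1)
  expect_error(r2_from_dosages(x, rep(1, 5)), "variance")
  expect_error(r2_from_dosages(x, c(0, 1, 2, 1, 3)), "\\[0, 2\\]")
  expect_error(r2_from_dosages(c(0, 1), c(1, 0)), "length")

  set.seed(11)
  x <- runif(100, 0, 2)
  y <- pmin(pmax(0.4 * x + runif(100, 0, 1), 0), 2)
  n <- length(x)
  cov_xy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  var_x <- sum((x - mean(x))^2) / (n - 1)
  var_y <- sum((y - mean(y))^2) / (n - 1)
  expect_equal(r2_from_dosages(x, y), cov_xy^2 / (var_x * var_y),
               tolerance = 1e-12)
})

test_that("LD tables are symmetric and unknown pairs stay unknown", {
  ld <- ld_table(c("rs1", "rs2"), c("rs2", "rs3"), c(0.5, 0.9))
  expect_equal(ld_r2(ld, "rs1", "rs2"), 0.5)
  expect_equal(ld_r2(ld, "rs2", "rs1"), 0.5)
  expect_equal(ld_r2(ld, "rs3", "rs2"), 0.9)
  expect_true(is.na(ld_r2(ld, "rs1", "rs3")))
  expect_equal(ld_r2(ld, "rs1", "rs1"), 1)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_ld_table(ld, path)
  back <- read_ld_table(path)
  expect_equal(sort(back$r2), sort(ld$r2))
})

test_that("LD pruning keeps the strongest SNP of each correlated group", {
  snps <- tibble::tibble(snp_id = c("A", "B", "C"),
                         pvalue = c(1e-10, 1e-8, 1e-9))
  # no measured LD: everything retained
  expect_equal(sort(ld_prune(snps, ld_table())), c("A", "B", "C"))
  # A and B correlated: the smaller p-value wins
  ld <- ld_table("A", "B", 0.5)
  expect_equal(ld_prune(snps, ld), c("A", "C"))
  expect_error(ld_prune(tibble::tibble(snp_id = "A", pvalue = NA), ld),
               "p-value")
})

test_that("greedy pruning equals the exhaustive elimination oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    k <- sample(3:8, 1)
    ids <- paste0("rs", sample(1e6, k))
    snps <- tibble::tibble(snp_id = ids, pvalue = runif(k, 1e-12, 1e-6))
    ld <- random_ld_table(ids, density = 0.4, seed = seed + 100)
    expect_equal(ld_prune(snps, ld), ld_prune_oracle(snps, ld))
    # output independent of input row order
    shuffled <- snps[sample(k), ]
    expect_equal(ld_prune(shuffled, ld), ld_prune(snps, ld))
  }
})

test_that("proxy search honors priority, threshold, and tie-breaks", {
  ld <- ld_table(rep("target", 4), c("p1", "p2", "p3", "p4"),
                 c(0.95, 0.90, 0.79, 0.95))
  sources <- list(chip = c("p1", "p2"), gwas = c("target", "p3"))

  # target genotyped in a lower-priority source: identity proxy there
  expect_equal(find_proxy("target", sources, ld),
               list(proxy_id = "target", r2 = 1, source = "gwas"))

  # absent everywhere: best candidate above the strict threshold wins
  sources2 <- list(chip = c("p1", "p2"), gwas = c("p3"))
  got <- find_proxy("target", sources2, ld)
  expect_equal(got$proxy_id, "p1")
  expect_equal(got$r2, 0.95)
  # r2 = 0.79 never qualifies (threshold is strict)
  expect_null(find_proxy("target", list(gwas = "p3"), ld))
  expect_null(find_proxy("target", list(gwas = "p5"), ld))

  # tie on r2: lexicographically smaller id, checked by enumeration
  sources3 <- list(chip = c("p4", "p1"))
  cand <- c("p1", "p4")
  best <- cand[order(-c(0.95, 0.95), cand)][1]
  expect_equal(find_proxy("target", sources3, ld)$proxy_id, best)

  # priority source searched first even if a later one has higher r2
  ld2 <- ld_table(rep("target", 2), c("a", "b"), c(0.85, 0.99))
  expect_equal(find_proxy("target", list(s1 = "a", s2 = "b"), ld2)$source,
               "s1")
})
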