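# summarymr

Two-sample Mendelian randomization (MR) from GWAS summary statistics, built
around the question of whether genetically elevated body-mass index (BMI)
raises the risk of multiple sclerosis (MS). The package is for
epidemiologists and statistical geneticists who have paired SNP–exposure
and SNP–outcome association tables and want the standard summary-data MR
stack — harmonization, LD pruning and proxy substitution, Wald ratios,
fixed-effects inverse-variance-weighted (IVW) pooling, MR-Egger pleiotropy
regression, the weighted-median estimator, heterogeneity statistics,
declarative sensitivity analyses, and a bidirectional mode — with every
estimator testable against a generator of synthetic summary statistics with
known ground truth.

## The model

Each SNP *j* supplies an exposure effect γ̂ⱼ (SD of BMI per allele) and an
outcome effect Γ̂ⱼ (log-odds of MS per allele, reconstructed from published
OR and 95% CI). Under the instrumental-variable assumptions each SNP gives
a Wald ratio

    β̂ⱼ = Γ̂ⱼ / γ̂ⱼ,   SE(β̂ⱼ) = σ_Γⱼ / |γ̂ⱼ|

and the ratios are pooled with fixed-effects inverse-variance weights:

    β̂ = Σ wⱼ β̂ⱼ / Σ wⱼ,   SE(β̂) = (Σ wⱼ)^(-1/2),   wⱼ = 1/SE(β̂ⱼ)²

Pleiotropy diagnostics: MR-Egger fits Γ̂ = β₀ + β₁ γ̂ by weighted least
squares (a nonzero intercept β₀ indicates directional pleiotropy; the
slope β₁ is a pleiotropy-adjusted estimate), and the weighted median
interpolates the inverse-variance-weighted 50th percentile of the ratios,
consistent while >50% of the weight comes from valid instruments.
Heterogeneity is summarized by Cochran's Q and I² with a test-based
confidence interval.

The package ships a transcription of the published characteristics of the
70 BMI instruments (GIANT exposure betas; IMSGC Immunochip and
IMSGC/WTCCC2 MS odds ratios; 36 measured through r² > 0.8 proxies) as
`inst/extdata/bmi_ms_snps.tsv`, loadable with `load_bmi_ms_fixture()`.

## Worked example

```r
library(summarymr)

instruments <- fixture_instruments()   # 70 harmonized BMI-MS instruments
mr_all(instruments, n_boot = 5000, seed = 42)[,
  c("method", "or", "or_ci_low", "or_ci_high", "pvalue", "i2")]
#>            method   or or_ci_low or_ci_high   pvalue i2
#> 1       IVW_fixed 1.41     1.197       1.66 3.59e-05  0
#> 2 Egger_intercept 1.00     0.989       1.01 8.94e-01 NA
#> 3     Egger_slope 1.37     0.919       2.05 1.21e-01 NA
#> 4  WeightedMedian 1.43     1.108       1.84 5.93e-03 NA
```

Reading: one SD of genetically determined BMI raises the odds of MS by
about 41% (IVW OR 1.41, 95% CI 1.20–1.66) with no detectable heterogeneity
across instruments (I² = 0). The Egger intercept (shown OR-scale, 1.00;
0.0008 on the log-odds scale) sits at the origin — no evidence of
directional pleiotropy — and its slope (1.37) and the weighted median
(1.43) agree in direction and magnitude with the IVW estimate.

The sensitivity battery and plot-ready tables:

```r
suite <- run_suite(instruments)        # all SNPs / AF-band proxies out / proxies out
forest_data(suite)                     # one OR row per analysis x method
run_pipeline("results_dir", fixture = TRUE)   # full bundle + run.log
```

A synthetic study with known truth:

```r
ds <- generate_dataset(simulation_config(k = 70, beta_causal = log(1.41),
                                         seed = 1))
mr_ivw(ds$instruments)$beta            # recovers ~log(1.41)
```

A thin CLI over the same functions lives at `inst/scripts/summarymr`
(subcommands `run`, `simulate`).

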