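---
title: "Two-sample Mendelian randomization with summarymr: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with summarymr: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", message = FALSE)
library(summarymr)
```

## The question and the framework

Observational cohorts report that elevated body-mass index (BMI) in early
life is associated with multiple sclerosis (MS), but confounding and reverse
causation are hard to exclude. Mendelian randomization (MR) side-steps both
by using genetic variants as instrumental variables: alleles are assorted
randomly at meiosis, so a SNP that raises BMI is, under the instrumental
assumptions, unconfounded with environmental causes of MS, and MS onset
cannot alter germline genotype.

`summarymr` implements the two-sample flavour of this design, in which the
SNP–exposure associations ($\hat\gamma_j$, SD of BMI per allele, from a BMI
GWAS meta-analysis) and the SNP–outcome associations ($\hat\Gamma_j$,
log-odds of MS per allele, from MS case–control consortia) come from
different samples and only summary statistics are needed. The package ships,
as a worked dataset, a transcription of the published characteristics of the
70 BMI instruments used in the source analysis (GIANT exposure effects,
IMSGC Immunochip / IMSGC-WTCCC2 outcome odds ratios), so every estimator in
the package can be exercised against published results without any
download.

## Estimators

**Wald ratios.** Each SNP contributes
$\hat\beta_j = \hat\Gamma_j / \hat\gamma_j$, the causal log-odds of MS per
SD of BMI, with first-order delta-method standard error
$\sigma_j = \sigma_{\Gamma j} / |\hat\gamma_j|$. Exposure-side uncertainty
is ignored (the NOME approximation). This is deliberate: it is the standard
practice for genome-wide-significant instruments, whose exposure SEs are an
order of magnitude smaller than their effects, and it is the only SE
reconstructible from a published instrument table that prints no exposure
SEs. Where an exposure SE is needed anyway — the weighted-median bootstrap
and the synthetic generator — and the table provides only beta and p, the
package reconstructs $\sigma_{\gamma j} = |\hat\gamma_j| / z(p_j)$.

**Fixed-effects IVW.** The primary pooled estimate is the inverse-variance
weighted mean of the ratios, $\hat\beta = \sum w_j \hat\beta_j / \sum w_j$
with $w_j = 1/\sigma_j^2$ and $\mathrm{SE} = (\sum w_j)^{-1/2}$. This is
algebraically the slope of a zero-intercept weighted regression of
$\hat\Gamma$ on $\hat\gamma$ with weights $1/\sigma_{\Gamma}^2$ — an
identity the test suite asserts to $10^{-10}$ against an independent
normal-equations solver. A fixed-effects (not random-effects) model is the
only pooling offered, matching the source analysis.

**Heterogeneity.** Cochran's $Q = \sum w_j(\hat\beta_j - \hat\beta)^2$ with
$k-1$ degrees of freedom, and $I^2 = \max(0, 100(Q - df)/Q)$. The $I^2$
confidence interval uses the test-based method on $\ln H$
($H^2 = Q/df$, $H$ truncated at 1) with back-transformation to the $I^2$
scale, truncated to $[0, 100]$. The method is not named in the source
report; this choice reproduces the published "0% (0–29)" on the packaged
data (the package computes an upper bound of 28.5).

**MR-Egger.** Weighted least squares of $\hat\Gamma$ on $\hat\gamma$ with a
free intercept and weights $1/\sigma_\Gamma^2$. The intercept estimates the
average direct (pleiotropic) effect; the slope is a pleiotropy-adjusted
causal estimate, consistent under InSIDE (instrument strength independent
of direct effects). The regression is not invariant to per-SNP allele
relabelling, so instruments are first re-oriented to non-negative exposure
effects; the packaged table is already oriented this way. Inference is
normal-theory on the WLS coefficients.

**Weighted median.** Ratios are ordered, inverse-variance weights
normalized, and the estimate is linearly interpolated at the half-weight
position of the cumulative midpoints $S_j - w_j/2$. The estimator is
consistent while more than half the total weight comes from valid
instruments. Its SE comes from a parametric bootstrap (default 5000
replicates, seed 42, both configurable): exposure and outcome effects are
resampled from normal distributions with their SEs and the whole
ratio-weight-median computation repeated.

A note on conventions: the interpolated weighted median is not the
minimizer of the weighted $L_1$ loss $\sum w_j |x - \hat\beta_j|$. That
minimizer — the classical, non-interpolated weighted median — always sits
at a data point, and the two coincide exactly only when the half-weight
position falls on a cumulative midpoint (equal weights with odd $k$ being
the familiar case). The tests validate the implementation against a grid
search of the $L_1$ loss in that regime and bound the difference by one
inter-point gap in general.

**p-values** are two-sided normal, floored at the smallest positive normal
double so serialized results never contain an exact zero. p-values are
reported, never used for gating inside the package, and no multiplicity
correction is applied (none was applied in the source analysis).

## Harmonization, proxies, pruning

Allele harmonization (`harmonize_pair`) supports two modes. In `"alleles"`
mode both records carry effect/other alleles; outcome effects are copied,
sign-flipped (with allele-frequency complementation) when the alleles are
swapped, matched through strand complement when reported on opposite
strands, and rejected when irreconcilable. Palindromic SNPs (A/T, C/G) with
allele frequency in $[0.4, 0.6]$ cannot be resolved from alleles alone and
are flagged, never dropped — the analyst decides, and the package's
analogue of that decision is the allele-frequency-band sensitivity filter.
In `"pre_oriented"` mode (used for the packaged table, which prints only
the BMI-increasing allele) records are taken as already aligned.

Outcome odds ratios are converted to log-odds with
$\mathrm{SE} = (\ln \mathrm{CI}_{hi} - \ln \mathrm{CI}_{lo}) / (2 z_{0.975})$,
$z_{0.975} = `r signif(qnorm(0.975), 7)`$ — the full-precision quantile
rather than 1.96, so the transform is exactly invertible.

LD pruning (`ld_prune`) enforces mutual independence of instruments:
candidates are ranked by exposure p-value (ties broken lexicographically
for determinism) and accepted greedily unless a measured $r^2$ with an
already-accepted SNP exceeds 0.05. Pairs absent from the LD table are
treated as independent — the source analysis measured all pairs, but
general inputs may not, and refusing to prune on unknown LD is the
conservative choice for instrument count. Proxy search (`find_proxy`)
scans outcome sources in priority order and requires $r^2 > 0.8$ (strict);
within a source the highest-$r^2$ candidate wins, ties broken
lexicographically. Validation of already-built instruments accepts
$r^2 \ge 0.8$ because published tables round to two decimals (the packaged
table prints one proxy at exactly 0.80).

The allele-frequency band filter flags instruments that are *proxied* and
have effect-allele frequency in the closed interval $[0.4, 0.6]$; directly
genotyped instruments are never flagged. The closed interval reproduces the
published 63-instrument / 29-proxy sensitivity subset. Proxy status comes
from the proxy column of the instrument table, not from the printed $r^2$
(seven published proxies have $r^2$ that rounds to 1.00).

## Sensitivity suite and bidirectional mode

`run_suite` executes a list of declarative `analysis_spec`s — ordered
filters (`drop_proxies`, `drop_af_band_proxies`, `drop_height_ld`,
`restrict_source:<label>`) plus an estimator set — and returns one row per
analysis-by-method. A spec that filters below three instruments is marked
failed and the suite continues. The default suite is the published battery:
all instruments, ambiguous-frequency proxies excluded, all proxies
excluded.

The height-LD filter is implemented generically (the concern: BMI combines
weight and height, so instruments correlated with height loci could
confound); the published list of six excluded SNPs lives in an unavailable
supplement, so this filter — like the single-source restriction — is
exercised on synthetic LD tables only, and their published ORs are not
reproduction targets.

Bidirectional analysis reverses the roles (MS liability as exposure, BMI as
outcome) and runs the identical stack; results carry a direction label and
SD-per-log-odds units. The source analysis used 99 MS instruments that are
not printed anywhere, so the mode is validated on synthetic data: under a
true null the reverse IVW CI covers zero at nominal rates, and at the
published effect scale (≈ −0.003 SD per log-odds) power is below 20%,
which is why a null finding there is the expected outcome.

```{r fixture}
instruments <- fixture_instruments()
mr_ivw(instruments)[, c("or", "or_ci_low", "or_ci_high", "pvalue", "i2")]
```

## The synthetic-data generator

`generate_dataset` draws paired summary statistics under a linear causal
model with optional pleiotropy: true exposure effects
$\gamma_j \sim |N(0.027, 0.012)|$, measured effects with
$\sigma_{\gamma j} \sim U(0.003, 0.005)$, outcome effects
$\Gamma_j = \beta \gamma_j + \alpha_j$ observed with
$\sigma_{\Gamma j} \sim U(0.015, 0.041)$, allele frequencies
$U(0.05, 0.9)$, and 36/70 of instruments labelled as proxies with
$r^2 \sim U(0.8, 1)$. Every default mirrors the packaged 70-SNP set:
effect moments match the printed exposure betas; the exposure-SE band is
the central 10th–90th percentile of the SEs reconstructed from printed
p-values (consortium exposure SEs cluster tightly just above the
genome-wide-significance floor, with a thin upper tail the uniform range
deliberately omits); the outcome-SE band is the min–max of the CI-derived
SEs. Direct effects $\alpha_j$ are drawn independently of $\gamma_j$, so
InSIDE holds by construction; an explicitly labelled `inside_violation`
mode correlates them (r = 0.8) to demonstrate where MR-Egger fails.
Outcome noise is Gaussian on the log-odds scale — the summary-statistic
regime — with no individual-level logistic simulation, no LD between
simulated instruments (real instruments are pruned to near-independence),
and no population-structure effects. Passing calibration tests on these
data therefore demonstrates estimator correctness under the stated model,
not robustness to stratification, sample overlap, or selection effects in
real consortium data.

Generated datasets round-trip bit-exactly through the package's TSV/JSON
formats and are byte-identical for a fixed seed; seeded generation restores
the caller's RNG stream.

## Calibration results and an honest limitation

The test suite verifies, at the study's own scale ($k = 70$, SE bands
above, $\beta = \ln 1.41$): IVW mean bias below 0.01 with CI coverage
inside [93%, 97%] (3000 replicates — enough that the Monte-Carlo error of
the coverage estimate, ~0.4 points, is small against the band), and
Egger-intercept type-I error inside [0.03, 0.07] under no pleiotropy
(2000 replicates). The small residual IVW attenuation (~ −0.005) is the
expected errors-in-variables effect of ignoring exposure noise under NOME.

Two published quantities do **not** reproduce from the printed table, and
the package reports them as computed rather than as published:

* *Weighted-median point estimate.* The source reports OR 1.26; the
  packaged table yields 1.43. The table prints MS odds ratios to two
  decimals, so eleven instruments print OR = 1.00 and contribute Wald
  ratios of exactly zero — a tie mass spanning a third of the total weight
  directly below the half-weight point. An order statistic cannot average
  this rounding away the way the IVW and Egger means do (those reproduce
  to within 0.01–0.03). With unrounded consortium effects the zero mass
  would spread and the median would plausibly land near the published
  value.

* *Weighted-median robustness at study-scale noise.* With outcome SEs of
  0.015–0.041 against exposure effects of 0.01–0.06, a single Wald ratio
  carries noise with SD ≈ 0.6–2 on the log-odds-per-SD scale. Directional
  pleiotropic shifts of realistic size are small against that noise, and
  in that regime the median's contamination bias tracks the mean's to
  first order: simulations at 30% invalid weight show the weighted-median
  bias reaching roughly 0.4–0.8 of the IVW bias across pleiotropy
  magnitudes, not the one-third or better that the asymptotic
  (shrinking-SE) theory promises. The weighted median remains valuable
  here as a directional consistency check — which is how the source
  analysis used it — rather than as a bias remover.

## Numerical and degenerate-input policy

Zero exposure effects make the Wald ratio undefined and raise an error
naming the SNP; the generator floors $|\gamma_j|$ at $10^{-6}$ for the same
reason. Degenerate CIs (zero width) are rejected by `or_to_log`. Exact
regression fits (zero residual) and single-replicate bootstraps produce
degenerate SEs; result rows handle these without poisoning p-values.
Heterogeneity needs $k \ge 2$ ($k \ge 3$ for the $I^2$ CI), Egger and the
weighted median $k \ge 3$. Unparseable numeric cells in input tables become
missing — never zero — with a warning when a record ends up with no usable
effect. All tie-breaks (pruning order, proxy choice) are lexicographic so
every pipeline output is reproducible row-for-row.

## Problem sizes used by the checks

Fixture analyses run on the 70-instrument table in well under a second.
Calibration uses 3000 replicates (IVW bias/coverage), 2000 (Egger type-I),
1000 (weighted-median vs IVW bias), 500 (reverse-direction null coverage
and power), and 5000 bootstrap replicates for weighted-median SEs — sizes
chosen so each Monte-Carlo standard error is comfortably below the
tolerance it guards.
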