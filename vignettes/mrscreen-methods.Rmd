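---
title: "Methods: two-sample MR screening in mrscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR screening in mrscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrscreen)
```

## The model and its assumptions

Two-sample Mendelian randomization estimates the causal effect of an
exposure on an outcome from two independent GWAS. For each instrument
SNP $j$ we observe $(\hat\gamma_j, \sigma_{\gamma j})$ — its estimated
per-allele effect on the exposure — and $(\hat\Gamma_j, \sigma_{\Gamma j})$
on the outcome. The working model is

$$\Gamma_j = \beta\,\gamma_j + \alpha_j,$$

with $\beta$ the causal effect and $\alpha_j$ a direct (horizontally
pleiotropic) effect. Valid instruments require (1) association with the
exposure, (2) independence from confounders, and (3) effects on the
outcome only through the exposure ($\alpha_j = 0$). The three estimators
trade robustness against these assumptions differently:

- **IVW** is the weighted least-squares slope of $\hat\Gamma$ on
  $\hat\gamma$ through the origin with weights
  $w_j = 1/\sigma_{\Gamma j}^2$, algebraically identical to the
  inverse-variance weighted average of per-SNP Wald ratios
  $\hat\Gamma_j/\hat\gamma_j$ with weights
  $\hat\gamma_j^2/\sigma_{\Gamma j}^2$ (an identity the test suite asserts
  numerically). It is unbiased when pleiotropy is absent or balanced.
- **MR-Egger** adds an intercept after orienting every SNP to
  $\hat\gamma_j > 0$; under the InSIDE assumption the intercept estimates
  the mean direct effect and the slope remains consistent under
  directional pleiotropy.
- **Weighted median** interpolates the weighted empirical quantile
  function of the Wald ratios at probability 0.5 (weights
  $\hat\gamma_j^2/\sigma_{\Gamma j}^2$ normalized, cumulative midpoint
  convention) and is consistent while at least half the weight comes from
  valid instruments. Its SE is a parametric bootstrap over
  $(\hat\gamma_j^*, \hat\Gamma_j^*)$, which is why a seed is mandatory.

For binary outcomes all effects are on the log-odds scale and results are
also reported as odds ratios per SD of exposure.

## Pipeline order and filtering rules

`run_pair()` composes the stages as: p-value screen → LD clumping →
harmonization → Steiger filter → weak-instrument filter → estimation →
diagnostics → classification. Placing the F filter after Steiger follows
the narrative order of instrument-selection procedures for metabolite
screens; because both filters are per-SNP predicates on the same record,
the surviving set is the same in either position — the alternative order
is available via `f_filter_stage = "pre_harmonize"` and a test asserts the
equivalence. Specific conventions, chosen for determinism:

- The p-value screen is a strict inequality (`pval < threshold`).
- Clumping is greedy by ascending p (ties broken by chromosome, then
  position), removing same-chromosome SNPs within ±window having
  r² ≥ threshold with the index; SNP pairs absent from the LD table count
  as independent. The window never spans chromosomes.
- Duplicate marker ids at read time keep the record with the smallest
  p-value.
- Palindromic (A/T, C/G) SNPs are removed unconditionally rather than
  rescued by allele-frequency comparison — frequency rescue trades a known
  small bias for extra SNPs and is deliberately not offered.
- Steiger filtering is a deterministic comparison
  $R^2_{out} > R^2_{exp}$ using the same variance-explained formula on
  both sides; no significance test is layered on top. For binary outcomes
  the outcome-side quantity is a pseudo-$R^2$ on the log-odds scale, so
  the comparison is conservative in units but monotone — a documented
  limitation.
- The F filter removes F **strictly below** the floor; F exactly 10 is
  retained. F is computed per SNP with $k = 1$ (the only reading under
  which an F threshold can remove individual SNPs); the joint-$k$ F of the
  final set is also reported as an attribute.

## Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `pval_threshold` | 1e-5 | instrument screen; relaxed because molecular traits often lack genome-wide-significant hits |
| `clump_r2`, `clump_window_kb` | 0.001, 10000 | LD pruning stringency |
| `f_min` | 10 | weak-instrument floor (per-SNP F) |
| `alpha` | 0.05 | gates and nominal tier |
| `n_tests` | number of exposures | Bonferroni tier divisor, applied per outcome |
| `n_boot` | 1000 | weighted-median bootstrap replicates |
| `n_sim` | 1000 | global-pleiotropy-test simulation rounds |
| `seed` | — | mandatory; per-pair sub-seeds derived deterministically |

## Numerical choices

- **IVW variant.** Multiplicative random effects: the fixed-effect SE is
  scaled by $\max(1, \hat\phi)$, $\hat\phi^2$ the weighted residual mean
  square on $J-1$ df. A fixed-effect variant is a flag. IVW p-values are
  normal; MR-Egger uses $t_{J-2}$ for both slope and intercept, with the
  same $\max(1,\hat\phi)$ scale on $J-2$ df. A consequence worth knowing:
  under an exact null with homogeneous instruments the floor makes the
  Egger-intercept test conservative (its true size is ≈ 0.034 at
  $J = 26$ rather than 0.05); under genuine balanced pleiotropy the floor
  is inactive and the test is essentially nominal — the suite measures
  both behaviours.
- **Cochran's Q** always re-centers on the fixed-effect IVW estimate of
  the set actually supplied (a regression test guards against reusing a
  stale center), and is referred to $\chi^2_{J-1}$.
- **Global pleiotropy test.** Leave-one-out IVW slopes give out-of-sample
  residuals; the observed weighted RSS is compared with `n_sim` parametric
  simulations under the no-pleiotropy model. The p-value uses the
  $(1 + \#\{RSS^* \ge RSS\})/(1 + n_{sim})$ convention so it is never
  exactly zero; per-SNP outlier p-values are Bonferroni-adjusted. SNPs are
  internally sorted by id before simulation so the result is invariant to
  row order under a fixed seed. The optional outlier-corrected
  re-estimation is not part of the screening gates.
- **Degenerate inputs.** Empty harmonized sets, insufficient instruments
  (Egger and weighted median need 3, the global test 4) and collinear
  Egger designs raise typed conditions; `run_pair()` converts them to a
  `skipped`/partial result with the stage recorded, never a crash. A
  single-SNP IVW reduces to the Wald ratio. P-values are floored at the
  smallest positive double rather than underflowing to zero.

## The synthetic-data generator

`simulate_pair()` works at the summary-statistic level: it draws MAF
$\sim U(0.05, 0.5)$, true instrument effects on the exposure-increasing
allele, direct effects $\alpha_j$ per pleiotropy mode, sets
$\Gamma_j = \beta\gamma_j + \alpha_j$, and observes each estimate as truth
plus normal noise with SE $1/\sqrt{2Np(1-p)}$ for standardized continuous
traits (scaled by $1/\sqrt{cf(1-cf)}$ on the log-odds scale for a binary
outcome with case fraction $cf$). Exposure and outcome samples are
disjoint by construction, so errors are independent between tables.
Defaults emulate a metabolite-GWAS setting: exposure sample size 8,299
with standardized traits; instrument effects $|\gamma| \sim U(0.1, 0.6)$
SD/allele, which at that sample size corresponds to per-SNP F statistics
of roughly 20–1000, the range reported for metabolite instruments;
outcome GWAS of $10^5$–$10^6$ samples. Effects are generated on the
exposure-increasing allele (all $\gamma_j > 0$): allele orientation is
arbitrary in real data, and a fixed positive orientation is what makes
"directional" pleiotropy well-defined for the Egger intercept — with
sign-symmetric $\gamma$, orientation would cancel any directional mean.
Half the outcome records are emitted allele-swapped to exercise
harmonization the way independently processed GWAS do.

What the generator deliberately does **not** emulate: correlation between
effect estimates of SNPs in the same LD block (the LD table is exact, but
estimates are drawn independently), winner's-curse selection in the
exposure GWAS, allele-frequency estimation error, population
stratification, and sample overlap. Passing calibration tests therefore
demonstrates correctness of the estimators and pipeline under the stated
model, not robustness to those real-data artefacts.

Scenario presets (`scenario_suite()`) fix the study conditions used by the
validation suite: `null`, `causal` ($\beta = 0.2$, 50 instruments,
outcome $n = 5\times10^5$), `balanced_pleiotropy` /
`directional_pleiotropy` ($\alpha_j \sim N(0, 0.01)$ vs
$N(0.02, 0.01)$), `weak_instruments` (effects straddling F = 10) and
`one_outlier` (one outcome effect displaced by 10 SE). With 26 instruments
these mirror the median instrument count of metabolite screens.

## What the validation computes

The acceptance suite and `scripts/acceptance.R` use problem sizes chosen
to give tight Monte-Carlo error at desk scale: 1000 replicates for
type-I-error calibration (global test at `n_sim = 200`), 200 replicates
for causal recovery and for pleiotropy discrimination, 200 random sets for
oracle equivalence, and a 10 × 2 screen for byte-level determinism. Under
the null scenario the IVW z-statistic, Q, and the Egger t-statistic are
exactly pivotal conditional on the exposure estimates (the outcome
estimates are pure noise), so Q follows $\chi^2_{J-1}$ regardless of
instrument strength; under a nonzero causal effect the ratio variance
acquires a $\beta^2\sigma_{\gamma}^2$ component that the weights ignore,
which the multiplicative random-effects SE absorbs. The small
weak-instrument attenuation of IVW (order $\sigma_\gamma^2/\gamma^2$,
about 0.3 % of $\beta$ under the causal preset) is visible as 95 % CI
coverage slightly below nominal.

## Known limitations

- No proxy-SNP lookup for instruments absent from the outcome GWAS, and
  no reference-panel strand inference beyond the complement rule.
- Instruments are modelled as independent after clumping; correlated-
  instrument (generalized least squares) estimators are out of scope, as
  are modal estimators, multivariable MR and reverse-direction screens.
- The Steiger comparison on binary outcomes mixes an observed-scale
  pseudo-$R^2$ with a continuous-trait $R^2$; with very unbalanced case
  fractions this becomes increasingly conservative.
- The Bonferroni tier corrects across exposures within each outcome, not
  across outcomes.
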