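---
title: "Resilience phenotyping from longitudinal AFS data: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resilience phenotyping from longitudinal AFS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resilpig)
```

# The deviation model of resilience

A growing pig's weight follows a smooth trajectory; feed intake and feeding
behaviour fluctuate around animal-specific levels. The working hypothesis of
deviation-based resilience phenotyping is that an animal which deviates
little from its own expected trajectory copes better with environmental
disturbances. The package turns daily automated-feeding-station (AFS)
records into per-animal deviation statistics, estimates their genetic basis
with animal models, and quantifies how stable those statistics are under
masking, thinning and window-shortening designs.

## Expected trajectories

Three references for "expected" are used, each with different failure
modes:

* the animal's **own Gompertz curve** `W(t) = A e^{-B e^{-kt}}` (increasing
  parameterization, `A` the mature weight, `k` the maturation rate; the
  curve is fitted by nonlinear least squares on the AFS window, optionally
  anchored by birth, 14-d and start/end-of-test weights). Deviation traits:
  `lnvar_weight`, `skew_weight`, `lag1_weight`. The curve is estimated from
  the same data it judges, so a strongly perturbed animal drags its own
  expectation towards the disturbance and the residuals understate it;
* the animal's **own straight line** on age (weight, feed intake, visit
  duration, visit count), giving `lnMSE_*`. We use MSE = RSS/n, the
  maximum-likelihood residual variance, so `lnMSE` is on the same scale as
  `lnvar` and its additive SD can be read directly as a genetic coefficient
  of variation;
* the **population**, via per-day z-scores of weight
  (`lnvar_weight_standardized`) and via a pooled 5 % quantile regression of
  feed intake and visit duration on age (`QR_FI`, `QR_dur`, counts of days
  strictly below the fitted line). These avoid the self-reference
  circularity entirely.

Trajectory analysis treats the weight series as a path in the (age d,
weight kg) plane: `straightness` is the start-to-end Euclidean distance over
the path length (exactly 1 for any collinear series, lower when the path
wiggles) and `mean speed` the path length over the age span (exactly 1 for
daily records of constant weight; growth and deviations both raise it, and
`straightness × mean speed × age span` always equals the start-to-end
distance). These need no model at all, at the price of conflating growth
rate with deviation level.

## Genetic model

All traits are analysed with the animal model `y = Xb + Za + Wc + e`:
fixed sex, farm and maximum-age effects; additive values
`a ~ N(0, K σ²_a)` with K a pedigree (A), genomic (VanRaden's first
method) or single-step (H) relationship matrix; contemporary groups
(farm × compartment × entry date, groups under 10 merged) as
`c ~ N(0, I σ²_c)`; and `h² = σ²_a / (σ²_a + σ²_c + σ²_e)`. For the
ln-variance traits the additive SD itself estimates the genetic coefficient
of variation of the underlying multiplicative variability, which is why
`gcv()` returns `sqrt(σ²_a)` for log-scale traits; the exact lognormal
form `sqrt(exp(σ²_a) − 1)` is nearly identical at the σ²_a ≈ 0.05–0.1
magnitudes seen here and we keep the simpler convention.

### How REML is computed

The restricted log-likelihood is maximized directly: each evaluation
assembles the sparse mixed-model equations, takes one CHOLMOD Cholesky
factorization, and uses
`log|V| + log|X'V⁻¹X| = log|R| + log|G| + log|M|` together with
`y'Py = y'R⁻¹y − r'ŝ`, so a full likelihood evaluation costs one sparse
factorization (milliseconds at a few thousand equations). Optimization runs
on the log-variance scale (L-BFGS-B, Nelder-Mead fallback), which keeps
variances positive without explicit boundary handling; convergence
tolerance 1e-8 on the parameters, cap 500 evaluations. A classical EM-REML
implementation (`method = "em"`, dense, with the guaranteed monotone
likelihood of EM) is kept for small problems and as a cross-check: both
methods maximize the same criterion and the test suite verifies they agree
with a brute-force grid search of an independently coded dense restricted
likelihood. Standard errors come from the inverse numerical observed
information with a delta-method step for ratios (h², c²) and for the
genetic correlation.

The bivariate model stacks two traits with a 2×2 additive covariance
(Kronecker with K) and a 2×2 contemporary-group covariance, and fixes the
residual covariance at zero so traits measured on overlapping animals stay
well-defined; this also means any residual-level dependence between two
traits derived from the same records is channelled into the genetic and
group components, a deliberate structural simplification. Both covariance
matrices are parameterized by their log-Cholesky factors, so they remain
positive semi-definite by construction and no projection step is needed.

Single-step H⁻¹ uses the standard construction
`A⁻¹ + [0 0; 0 G*⁻¹ − A22⁻¹]` with `G* = 0.95 (βG + α) + 0.05 A22`, where
(α, β) match G's mean diagonal and mean off-diagonal to A22. The 0.95/0.05
blend and the scaling are conventional defaults (both configurable); the
dense-assembly identity is verified to 1e-8 in the tests.

## Cross-validation and robustness designs

Masking follows three designs: within-family (each sire's offspring split
over 5 folds), across-family (whole sire families masked together) and
temporal (animals born after a cutoff). Phenotypes are adjusted once, on
the full data, to `y* = y − Xb̂ − Wĉ`; variance components are also fixed
at their full-data estimates and only the mixed-model equations are
re-solved per fold. Re-estimating components per training fold would be
defensible too, but with 20 % masking the estimates barely move and the
fixed-component version keeps all 50 fits (10 replicates × 5 folds)
internally consistent. Predictive ability is `r(EBV_masked, y*)` over
masked animals and accuracy divides by √h² of the same relationship matrix.

Observation-frequency designs keep 1 record in every 4, 7 or 14 by position
in each animal's age-sorted series (offset 0, so the first record is always
kept); observation-period designs split the 95–155 d window into
left-closed 20-day periods [95,115), [115,135), [135,155] — the boundary
days 115 and 135 belong to the later period. Robustness is summarized by
the Pearson correlation between the full-data and reduced-data versions of
each trait and, where a relationship matrix is supplied, by their genetic
correlation from the bivariate model.

One estimator detail matters for thinned data: the lag-one autocorrelation
pairs records separated by the series' modal spacing. On daily data that
spacing is 1 d, so a QC-created hole breaks the pair instead of treating
records days apart as adjacent; on a 1-in-k thinned series consecutive
records pair at lag k. Without this rule the trait would be degenerate (no
adjacent days exist) as soon as records are thinned.

# The synthetic data generator

No AFS dataset of this kind is publicly deposited, so the package generates
its own, with every assumption explicit and every corruption logged.

**Population.** Three generations: a grandparent founder pool, the sires
and dams of the recorded animals (gaining half-sib structure through the
grandparents — without it, across-family and temporal masking would leave
masked animals with no phenotyped relatives at all, which no deep-pedigree
population resembles), and the recorded generation: one litter per dam,
dams split round-robin over sires, litters housed as batches in pens of 15,
compartments of 10 pens, one entry date per compartment spaced 14 days,
compartments alternating between two farms. A contemporary group is a
farm × compartment × entry-date cell.

**Growth and feeding.** Each animal's Gompertz parameters are
mean + additive + environmental, with per-parameter heritability 0.3
(defaults A = 225 ± 25 kg, B = 6.75 ± 0.8, k = 0.0148 ± 0.0018 /d and the
negative A–k, positive B–k correlations typical of finishing pigs; these
curve means put weights near 43 kg at 95 d and 114 kg at 155 d). The
contemporary-group effect (SD 8 kg) shifts the asymptote. Feed intake is
maintenance (15 g/d per kg) plus expected gain times 1.1 g/g. Daily weight
noise is i.i.d. with animal-specific SD `exp((mu_v + v_i)/2)`, where the
log-variance `v` is purely additive with variance `sigma2_av = 0.2` — the
exponential (multiplicative) model under which the additive SD of a
ln-variance trait is its GCV.

The baseline `mu_v = −0.6` (daily SD ≈ 0.74 kg) is a deliberate
calibration: AFS scales are accurate to ~0.5 kg, and a 3-kg outlier band
that discards only on the order of 1 % of records — as the field's QC
reports do — is only coherent if clean daily noise stays well below 1 kg.
Field estimates of `lnvar_weight` are higher than this generator produces
because real residuals also contain slow, autocorrelated biological
excursions that the generator represents only through discrete
perturbation events; passing tests therefore demonstrate correct recovery
of the stated generative model, not that real data are this tame.

**Perturbations.** Events arrive Poisson (0.6 per animal per window),
last geometrically ~5 days, and cut feed intake by a Beta-distributed
fraction (mean 0.3). The lost feed converts to a persistent weight-gain
deficit at 2,240 g feed per kg of gain, implementing the short-term
(intake) versus moderate-term (weight) response distinction; visit
duration drops with intake, and there is no compensatory growth. The event
model is one plausible choice — the underlying perturbation process of real
barns is not observable — and is labelled as such.

**Artifacts.** Weight spikes of 5–25 kg on 1 % of days, adaptation-phase
inflation of 20–60 kg (a penmate on the scale) over the first 3–6 days for
3 % of animals, 2 % missing days, 0.2 % gross errors outside 10–160 kg.
Every corrupted cell is ledgered, so QC sensitivity (corrupted cells
removed) and specificity (clean cells kept) are measurable exactly.

# Numerical and QC design choices

* **Boundary conventions** are literal: "below 10 kg" strictly,
  "more than 3 kg" strictly (with a 1e-9 numerical slack so an exact 3.000
  is kept), "exceeding mean + 4 SD" strictly, "gaps larger than ten days"
  strictly. Sample (n−1) variances everywhere except lnMSE (RSS/n by
  design); skewness is the population-moment g1 (adjusted Fisher–Pearson
  available by flag).
* **The rolling-median filter detrends first.** Pigs gain ≈1 kg/d, so at
  the ends of a series — where a centered 10-d window is necessarily
  one-sided — the raw rolling median lags the trend by up to half a
  window's growth and a fixed ±3 kg band flags clean records. The filter
  therefore applies the band to residuals from a per-animal quadratic fit,
  combining the rolling median with a second-order polynomial trend, with
  one MAD-trimmed refit so spikes and adaptation runs cannot leverage the
  trend; the window median is taken over trim-passing values so a
  multi-day corrupted run cannot dominate its own median. The filter
  iterates to a fixpoint, which makes the whole cascade idempotent. The
  raw-median variant remains available (`rolling_detrend = "none"`).
* **Pen screen.** Pens are flagged when their weight-on-age RMSE exceeds
  Q3 + 1.5 IQR of pen RMSEs (the printed procedure inspected outlying pens
  visually; the boxplot rule automates that judgement and is configurable).
  Within a flagged pen each animal is judged against its own robust trend,
  so between-animal level and slope differences are not mistaken for
  errors; flagged stretches shorter than 20 consecutive days are set
  missing, longer ones remove the animal.
* **Feed/behaviour limits** use one pass of mean + 4 SD on the current
  dataset, matching the single realized thresholds such procedures report.
* **Gompertz fitting** uses `nls` (port, positivity bounds) with a
  log-log-linearized start and a Levenberg–Marquardt fallback;
  non-convergence is flagged and the curve-based traits go missing rather
  than erroring. Residual-based traits use only in-window daily records
  even when anchors were fitted, so animals with and without anchors stay
  comparable.
* **Quantile regression** uses the Koenker check-loss fit (`quantreg`,
  Barrodale–Roberts at small n, Frisch–Newton at large n); "in the 5 %
  lowest quantile" means strictly below the fitted line. The tests verify
  the fit against exhaustive vertex enumeration at small n and the 5 %
  flag-rate property at n = 50,000.

# Problem sizes and what the tests show

The validation suite runs at deliberately moderate scale: heritability
recovery uses 10 replicates of 2,000 recorded pigs with 61 daily records
each (REML estimates of ADG and lnvar h² match the realized simulated
values to well within ±0.05), genetic-correlation recovery uses 4,000
half-sib offspring (r_g = 0.5 recovered within ±0.1), gene-dropping IBD
uses 10⁶ drops on a 12-animal inbred pedigree, and QC scoring uses a
200-pig barn with all artifact channels active (sensitivity ≥ 95 %,
clean-cell loss ≤ 1 %). These sizes make the whole suite run in minutes
while leaving the Monte-Carlo error comfortably below the tolerances
tested.

Known limitations: no social or pen-competition effects, no disease-agent
model, purely additive genetics (no dominance or inbreeding depression),
residual covariances fixed at zero in bivariate models, and a perturbation
process that is a modelling convention rather than an observed mechanism.
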