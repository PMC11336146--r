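---
title: "Directional signature scoring and optimal-cutoff survival scanning"
author: "SigScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directional signature scoring and optimal-cutoff survival scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SigScan)
```

## The model and its assumptions

SigScan implements a two-stage prognostic model for relapse-free survival
(RFS, in months) on gene-level microarray intensities.

**Stage 1 — directional screen.** Each gene is fitted alone in a Cox
proportional-hazards model. Only the *direction* of the fitted hazard
ratio is kept: weight +1 if HR > 1, −1 if HR < 1. This is deliberately
cruder than a penalized-coefficient signature: a ±1 rule is robust to the
scale and to moderate noise in the per-gene estimates, and makes the
signature portable across cohorts whose intensity scales differ. The
screen assumes proportional hazards per gene and independence of censoring
from expression; it does not assume linearity beyond what the sign
requires (any positive affine transform of a gene leaves its weight
unchanged, which the test suite checks as an invariant).

**Stage 2 — weighted-mean score and cutoff scan.** The signature score is
the average of weight × expression over signature genes, computed on
linear, per-array mean-1000 normalized intensities. Because any single
dichotomization point is arbitrary, every unique observed score value `v`
with Q1 ≤ v < Q3 is tried as a cutoff (low: score ≤ v, high: score > v).
Restricting to observed values is exhaustive — the risk-set composition,
and hence any test statistic, only changes at observed scores. Each
cutoff yields a high-vs-low hazard ratio and p-value; the scanned family
is corrected with the Benjamini–Hochberg (BH) step-up FDR, and the
reported cutoff is the raw-p minimizer. Selecting a minimum over ~n/2
correlated tests inflates the raw type-I error severely (the acceptance
suite measures the inflation directly under a global null); the adjusted
p-value of the selected cutoff is the quantity to trust.

Group orientation is fixed: HR > 1 always means "higher signature score,
worse outcome", at every cutoff, in every dataset.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `targetMean` | 1000 | per-array mean after scaling normalization, the conventional MAS5 scaling target; units are linear intensity |
| `qLow`, `qHigh` | 0.25, 0.75 | scan bounds as score quantiles (type-7, linear interpolation; configurable) — extreme cutoffs produce unstable tiny groups |
| `minGroup` | max(5, 10% of n) | additional guard against degenerate groups at admissible cutoffs |
| `test` | `"cox"` | per-cutoff test. A Wald p from the dichotomized Cox fit is the default because an HR is reported per cutoff; `"logrank"` is available and preferable when a cutoff separates the groups almost perfectly (the Wald statistic degenerates under a monotone partial likelihood) |
| `standardize` (screen) | `TRUE` | per-gene standardization before the univariate fit; the weight's sign is invariant to it, but standardized fits converge more uniformly across intensity scales |
| `medianSplit` (screen) | `FALSE` | screen on the median-dichotomized gene instead of the continuous value; continuous is the minimal-assumption default |
| `minN`, `minEvents` (per-dataset) | 30, 10 | dataset sufficiency filter; below either bound a within-dataset fit is too unstable to count as replication |
| QC thresholds | ratio ≤ 3, present ≥ 25%, spikes required | common microarray practice; all overridable via `qcThresholds()` |

Ties in the Cox partial likelihood use the Efron approximation
(more accurate than Breslow at the tie densities of rounded follow-up
times). Confidence intervals are Wald on the log-hazard scale with
z = 1.959964. P-values are reported in two-significant-digit scientific
style; full precision is retained internally.

## Covariate encodings and the paired models

Clinical covariates are frequently missing in integrated cohorts, so a
single multivariable model over all covariates would keep only a small
complete-case core. Instead the signature (dichotomized at the
whole-cohort selected cutoff) is paired with one covariate at a time on
that covariate's complete cases. Encodings: sex female=0/male=1; T, N,
stage, grade as ordinal integers; M 0/1; location proximal=0/distal=1;
MSI ordinal with stable=0, high=2 and the merged "stable or low" level at
0.5. Collinearity between the dichotomized signature and the encoded
covariate, constant covariates and fully missing covariates are rejected
with explicit errors, never silently fit.

Per-dataset replication uses one shared weight table screened on the
integrated cohort — re-screening per dataset would validate a different
signature in every dataset — while the cutoff is re-optimized within each
dataset by default (a fixed global cutoff is available via
`globalCutoff`), since the score distribution shifts with dataset batch
effects.

## What the synthetic cohorts emulate — and what they do not

`simConfig()` defaults describe a GEO-style integrated cohort: ten
datasets totalling 1130 samples, a censoring target of 0.76 (≈24% relapse
events), log-normal per-gene intensities with per-dataset multiplicative
batch shifts, per-array mean scaled to exactly 1000, and 40 risk plus 40
protective genes at |β| = 0.5 per SD among 200 genes. Hazards act on the
*within-dataset standardized* expression, so effect sizes are scale-free
while the raw matrix keeps realistic skewed scales — this deliberately
stresses the raw-scale weighted mean, where high-intensity genes dominate
the score. The baseline exponential rate (4e−4 events/month) is chosen so
that the realized follow-up under the default effect structure lands on
the tens-of-months scale of clinical RFS data. Censoring is an
administrative uniform window whose width is calibrated by bisection to
the target event fraction — simple, monotone and reproducible.

Simulated covariates are drawn at the frequencies of a large colon-cancer
cohort (male ≈ 53%, T3/4 and N0/1 dominating, mostly M0, stage 2–3 most
common, MSI mostly stable-or-low) with per-feature missingness matching
how sparsely such annotations are available; a confounded mode ties stage
to the hazard through a cumulative-logit shift for testing the paired
models under confounding.

Not emulated: gene–gene correlation beyond batch effects, probe-level
artifacts, non-proportional hazards, informative censoring, and cohort
heterogeneity in effect sizes. Passing tests on these cohorts therefore
demonstrates the *machinery* — sign recovery, FDR behaviour, replication
logic — not that any particular biological signature generalizes.

## Numerical choices and degenerate inputs

* Cox fits converge to relative tolerance 1e−9 within 100 iterations;
  monotone likelihood (perfect separation) is flagged
  (`converged = FALSE`), and flagged genes get weight 0 in the screen.
* Constant genes get weight 0 with reason `"constant"`; HR exactly 1
  (measure-zero in practice) also maps to 0, since the ±1 rule covers
  only HR > 1 and HR ∈ (0, 1).
* At tied times, events precede censorings in risk-set accounting (the
  standard convention).
* Tied minimum p in the scan breaks toward the cutoff nearest the median
  score — the most central, hence most stable, of the tied splits.
* BH adjustment validates p ∈ (0, 1] and is monotone and never below the
  raw p; it is not idempotent on arbitrary outputs (a fixed point only on
  families that collapse to a single adjusted value).
* Missing-value tokens in categorical columns are the empty string, "NA"
  and "NaN" case-insensitively; any other out-of-vocabulary label is an
  error, so vocabulary drift fails loudly instead of becoming silent
  missingness.
* QC flagging: `fail` iff any non-missing metric violates its threshold;
  `unevaluable` iff nothing violates but a required metric is missing;
  QC-failing arrays are excluded and unevaluable ones kept, both logged.

## Problem sizes used by the test and acceptance suites

The suites run entirely on generated data, sized to exercise the
asymptotics they check: 5–6-subject fixtures against hand-computed
product-limit, log-rank O−E/V and grid-search partial-likelihood oracles;
n = 5000 for Cox consistency at a known rate ratio 2; a 600-sample,
3-dataset cohort with 80 effect genes for sign recovery; 500 replicates
of an n = 200 global-null scan for the minimum-p inflation measurement;
and 1130 samples for the cohort-shape emulation. These sizes are the
package's own choices for stable Monte-Carlo assertions.

## Known limitations

* Per-array scaling is compositional: every gene's scaled value is weakly
  anti-correlated with the rest of the array. When a cohort carries many
  strong effect genes, this nudges the screened direction of truly null
  genes slightly negative — visible in the null-gene sign split of large
  simulations. The effect shrinks with the gene count and does not touch
  effect-gene sign recovery.
* The minimum-p cutoff remains an optimistic point estimate even with BH
  over the scanned family; permutation-based corrections for the selected
  cutoff (Lausen–Schumacher style) are not implemented.
* No stratified Cox, time-varying covariates, competing risks, or
  meta-analytic pooling of per-dataset hazard ratios.
* Probe-level preprocessing consumes an external chosen-probe table; the
  probe-ranking itself (JetSet-style scoring) is out of scope, as are
  MAS5 condensation and any data retrieval.
* XLSX gene lists are read via `readxl`; only the first sheet is used.

```{r example, eval = FALSE}
sim <- simulateCohort(simConfig(n_samples = c(150, 150, 150), seed = 42))
res <- analyzeCohort(sim$cohort)
res$scan
perDataset(sim$cohort, res$weights)
```
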