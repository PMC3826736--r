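---
title: "AD pattern similarity scores: model, estimation and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AD pattern similarity scores: model, estimation and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind the package, the
numerical choices made in its implementation, and the design and limits of
the synthetic cohort generator used for validation. Code chunks are shown
but not evaluated; the package test suite executes all of these computations
with assertions attached.

## 1. The model

The core quantity is the **AD pattern similarity (AD-PS) score**: the
class-conditional probability $P(\mathrm{AD} \mid x)$ produced by a
regularized logistic regression fitted on high-dimensional structural or
cognitive data. Two *anchor* classes train the model — cognitively normal
(CN, coded 0) and Alzheimer's disease (AD, coded 1) — and intermediate
subjects (mild cognitive impairment, MCI) are scored by the trained model.
Because the score is a probability, it lives in $[0,1]$ and is comparable
across modalities.

The fitted object minimizes the elastic-net penalized average negative
log-likelihood

$$
\frac{1}{n}\sum_{i=1}^{n}\Big[\log\big(1+e^{\eta_i}\big)-y_i\eta_i\Big]
\;+\;\lambda\Big(\alpha\lVert\beta\rVert_1+\tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2\Big),
\qquad \eta_i=\beta_0+x_i^\top\beta ,
$$

with the intercept unpenalized. The $\ell_1$ term produces sparse voxel
selections; the $\ell_2$ term stabilizes groups of correlated predictors.
Conventions follow the reference implementation of this objective family:
the loss is averaged (not summed) over subjects, and predictors are
standardized internally with the population (divide-by-$n$) standard
deviation, with coefficients reported on the original scale.

## 2. The solver

The solver is written in-package (C++ inner loops) because the estimator
*is* the method: iteratively reweighted least squares (IRLS) around the
current linear predictor, each weighted least-squares subproblem minimized
by cyclic coordinate descent with the soft-threshold update

$$
\beta_j \leftarrow
\frac{S\!\big(\tfrac{1}{n}\sum_i w_i x_{ij} r_i^{(j)},\ \lambda\alpha\big)}
     {\tfrac{1}{n}\sum_i w_i x_{ij}^2+\lambda(1-\alpha)},
\qquad S(u,t)=\operatorname{sign}(u)\,(|u|-t)_+ .
$$

Numerical safeguards, all surfaced as documented constants:

* probabilities are clipped to $[10^{-10}, 1-10^{-10}]$ and IRLS weights
  floored at $10^{-5}$, preventing division blow-ups near saturation;
* a step-halving line search on the true penalized objective guarantees
  monotone descent (the quadratic approximation alone does not);
* convergence is declared when the largest coefficient change in a full
  IRLS step falls below `tol` ($10^{-7}$ by default); non-convergence at
  `max_iter` raises a warning at the top level and is recorded in a
  `converged` flag inside search loops;
* coefficients below $10^{-9}$ (standardized scale) after convergence are
  flushed to exact zero, so sparsity counts are free of rounding residue —
  in particular the all-zero solution at $\lambda \ge \lambda_{\max}$ is
  exact.

Paths over decreasing $\lambda$ are warm-started, screened with a
sequential strong rule, and every screened solution is verified against the
full Karush–Kuhn–Tucker (KKT) conditions, so screening can never change an
answer — only speed it up. `kkt_residuals()` exposes the subgradient
residuals as a convergence certificate; the test suite checks them against
independent oracles (a proximal-gradient minimizer, the closed-form
soft-threshold solution on orthonormal designs, and an external reference
library as a cross-check only).

$\lambda_{\max}$, the smallest penalty with an all-zero solution, is
computed in closed form as
$\max_j |\tilde x_j^\top (y-\bar y)| / (n\alpha)$ on the standardized
design; automatic grids are log-spaced from $\lambda_{\max}$ down to
`lambda_min_ratio * lambda_max`.

## 3. Nested cross-validation and scoring

All performance numbers come from a three-way split: `K1` external folds
held out for testing; within each external training set, `K2` internal
folds pick $(\alpha, \lambda)$ by grid search; the model is refitted on the
full external training set at the chosen pair and evaluated on the held-out
fold. The procedure repeats with fresh stratified partitions
(`repetitions` times) and reports median accuracy, sensitivity and
specificity across repetitions. Defaults are `K1 = K2 = 10` and 100
repetitions; the worked examples and acceptance experiments use
`K1 = K2 = 5` with 10 repetitions, which preserves the protocol at desk
scale.

Selection uses the mean validation accuracy surface. Ties are broken
toward the **largest** $\lambda$, then the largest $\alpha$ — maximal
regularization among equally good models. An alternative `select =
"average"` rule averages the per-fold winning pairs instead of maximizing
the pooled surface; both are exposed because they answer slightly
different questions (a single consensus winner versus a partition-stable
compromise).

Anchor subjects are scored **out of fold**: each subject's score in a
repetition comes from the one external model that never saw it, and the
final AD-PS score is the median across repetitions. `audit_no_leakage()`
re-derives, for every subject and repetition, which external fold produced
its score and asserts it matches the subject's own held-out fold.
Non-anchor (MCI-like) subjects are scored by full-anchor-data models, one
per repetition with per-repetition re-selection, again median-aggregated;
the two provenances are recorded and never mixed.

## 4. Composites, the probability hypercube and risk zones

Per-modality scores for grey matter (GM), white matter (WM), cerebrospinal
fluid (CSF) and the cognitive battery place each subject in a unit
hypercube with that fixed axis order. Composites are exact unrenormalized
sums — Anatomical = GM + WM + CSF in $[0,3]$, Composite = Anatomical +
cognitive in $[0,4]$. Risk zones partition the hypercube with strict
inequalities: *low* when every coordinate is below 0.5, *high* when every
coordinate is above 0.5, *indeterminate* otherwise (a coordinate exactly
at 0.5 is never low or high). Distances to hypercube corners give a
continuous alternative to the trichotomy.

## 5. Discriminative maps

The weight ensemble refits the model on the full anchor data once per
repetition, with the regularization pair re-selected from that
repetition's internal CV partition. The **stability ratio** summarizes
each voxel as mean weight divided by the standard deviation
($n-1$ denominator) across repetitions. Degenerate voxels follow stated
rules: SD $=0$ with mean $=0$ maps to 0 (never selected); SD $=0$ with
mean $\neq 0$ maps to a signed sentinel $\pm 10^6$ and is flagged. Maps
are written back into masked volume space in fixed linear scan order
(fastest-varying first axis), and the vectorize/to-volume pair round-trips
exactly.

Sign convention: with labels CN $=0$ / AD $=1$ and atrophy coded as lower
intensity, a voxel whose atrophy predicts AD receives a negative weight.
The package records signs and leaves interpretation to the caller.

**Support recovery versus sparsity.** Max-accuracy selection with the
largest-$\lambda$ tie-break is a *sparsity-seeking* instrument: when a
planted effect is redundant (many voxels carrying the same signal), the
sparsest model that separates the classes wins, and most planted voxels
are individually expendable. For map experiments whose goal is recovering
the full planted support, the package instead uses a ridge-leaning mixing
parameter ($\alpha = 0.2$) over a fixed moderate penalty grid with the
per-fold-average selection rule; on the default synthetic cohort this
recovers ~98% of planted voxels in the top-$k$ ranking with perfect
precision, stably across seeds. Both protocols are correct; they answer
different questions.

## 6. Downstream statistics

Group separation of scores is tested with the two-sample
Kolmogorov–Smirnov statistic (asymptotic p-values; the statistic itself is
verified against a brute-force ECDF sup-difference in the tests).
Stratified tables report per-stratum medians and all pairwise KS p-values
without multiplicity adjustment, which is documented. Association of each
score metric with conversion time uses a Cox proportional-hazards model
with Breslow tie handling; the covariate is standardized internally so
hazard ratios are per 1 SD. Degenerate inputs (no events, zero variance)
are rejected; monotone-likelihood divergence is flagged.

## 7. The synthetic cohort generator

Real AD neuroimaging cohorts are access-restricted, so validation uses a
generator that reproduces the *statistical structure* the analyses assume,
with ground truth retained:

* **Groups and severity.** Four groups in severity order — CNsim,
  ncMCIsim, cMCIsim, ADsim, 40 subjects each by default — with graded
  effect fractions $(0, 1/3, 2/3, 1)$ and per-subject latent severity
  jittered around the group grade. Severity drives images, cognition, age,
  functional status (FAQ) and conversion hazard, so group gradients
  propagate to every signal-carrying output by construction.
* **Images.** Per tissue, a $20^3$ grid (8000 voxels) at baseline
  intensity 1.0, minus the group's decrement inside planted axis-aligned
  blocks (two per tissue, 27–125 voxels), plus i.i.d. Gaussian noise
  (`noise_sd = 0.15`). Decrements GM 0.35 / WM 0.25 / CSF 0.18 give a
  per-voxel effect ordering mirroring the empirical finding that grey
  matter is the most discriminative tissue.
* **Cognition.** A 25-score battery with named subscales; 10 scores carry
  a graded mean shift (2 noise-SD units at full severity).
* **Survival.** Exponential conversion times for the MCI-sim groups with
  log hazard linear in standardized severity (0.69 per SD, true hazard
  ratio 2.0), administrative censoring at a 36-month horizon, and random
  censoring topped up to a 30% overall target (within 5 points when
  attainable). The default baseline hazard (0.05/month) is chosen so
  administrative censoring alone stays *below* the target — top-up can
  only add censoring, never remove it.

**Realism and limits.** The generator is deliberately minimal: noise is
i.i.d. rather than spatially autocorrelated, planted effects are
homogeneous blocks rather than anatomically shaped atrophy patterns, and
per-voxel effect sizes are large relative to real voxel-based morphometry.
It validates *machinery* — recovery of planted supports, propagation of
severity gradients, leakage-free protocol behavior — not clinical effect
sizes. Headline numbers from real cohorts are not reproducible from it
and are not targeted.

## 8. Problem sizes and determinism

The package's own study conditions are desk-scale: $n = 160$ subjects,
8000 voxels per tissue, `K1 = K2 = 5`, 10 repetitions. A full four-modality
pipeline run completes in a few minutes on one CPU; individual fits on the
$80 \times 8000$ anchor matrix take well under a second thanks to the
screening rules.

All randomness flows from user-supplied integer seeds ($< 2^{31}$) through
`derive_seeds()`, which produces independent sub-seeds per stage and
repetition; `with_local_seed()` restores the caller's RNG stream.
Identical seed and configuration reproduce every output byte for byte; the
emitted `manifest.json` records the seed and a config hash, every output
table carries both, and `config_from_manifest()` rebuilds the exact
configuration for reruns.

```{r}
library(adps)
cohort <- simulate_cohort(cohort_spec(), seed = 1)
config <- run_config(K1 = 5, K2 = 5, repetitions = 10, seed = 1)
run <- run_pipeline(cohort, config, outdir = "results")
print(run)
```
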