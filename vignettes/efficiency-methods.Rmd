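---
title: "Measuring and explaining technical efficiency in jurisdiction panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and explaining technical efficiency in jurisdiction panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

jurisdea measures how efficiently administrative health jurisdictions turn
care resources into diabetes care, and asks which contextual conditions
(poverty, coverage, indigenous population share, demand, inequality,
government support, employment) explain the differences. The unit of
analysis is the jurisdiction-year: each year is treated as its own
cross-section with its own production frontier, so secular change in the
technology does not contaminate the within-year comparison.

## The efficiency model

Each jurisdiction converts 16 non-negative input rates (4 infrastructure,
12 human-resource categories, all per 10,000 inhabitants) into two
outputs: patients with diabetes under treatment and patients with
controlled diabetes. Technical efficiency is estimated by data envelopment
analysis (DEA) in the output-oriented Banker–Charnes–Cooper (BCC) form,
which allows variable returns to scale. For DMU 0 with inputs $x_0$ and
outputs $y_0$ the Farrell output distance solves the envelopment program

$$\max_{\theta,\lambda}\ \theta \quad \text{s.t.}\quad
Y^\top\lambda \ge \theta y_0,\quad X^\top\lambda \le x_0,\quad
\textstyle\sum_i \lambda_i = 1,\quad \lambda \ge 0 ,$$

with the convexity constraint dropped under constant returns. The DMU
itself is feasible at $\theta = 1$, so $\theta \ge 1$; the package reports
the score $1/\theta \in (0,1]$, matching the (0,1) magnitudes of published
efficiency series under output orientation. The paper-facing convention
(reciprocal score, one frontier per year rather than a pooled
intertemporal frontier) is an assumption of this package: published
sources often leave both unstated, and year-specific frontiers are what a
yearly efficiency series with confidence intervals implies.

The linear programs are solved by a dense two-phase simplex written for
this package (no LP library is required). Each program is pre-conditioned
by row scaling — inputs to the evaluated DMU's own levels, outputs to the
geometric mean of the DMU's level and the column mean — and by rescaling
the $\theta$ variable so its tableau column is $O(1)$; DEA is units
invariant, so none of this changes the score. Pivoting uses Dantzig's
rule with a largest-pivot tie-break, falling back to Bland's rule as an
anti-cycling safeguard. The solver is cross-checked in the test suite
against an exact vertex-enumeration oracle and a concave-hull
construction for the single-input case (tolerance 1e-6), and feasibility
is asserted at 1e-9.

Two operational details matter in practice. Input columns that are
entirely zero within a year (a facility type that has disappeared) are
vacuous constraints and are dropped for that year, with a message. And
with 16 inputs, 2 outputs and roughly 242 DMUs, the input dimension is
high relative to the sample — a well-known regime in which raw DEA scores
crowd toward 1. The package logs this but stays faithful to the full
variable set for the descriptive pipeline; ground-truth recovery checks
instead score on the two input aggregates that define the synthetic
technology (see below), which is the well-specified model for those
checks.

## Bias correction: the smoothed homogeneous bootstrap

DEA estimates the frontier from the same data it scores, so estimated
distances are biased toward the frontier (efficiency over-stated). The
package implements the classic smoothed homogeneous bootstrap: Farrell
distances live on $[1,\infty)$, so a kernel density estimate is formed on
the reflected sample $\{\theta_i\}\cup\{2-\theta_i\}$ with Silverman's
rule-of-thumb bandwidth $h = 0.9\,\min(\hat\sigma,
\mathrm{IQR}/1.34)(2n)^{-1/5}$. Each resample draws from the reflected
set, adds $h\varepsilon$ kernel noise, shrinks centered draws by
$1/\sqrt{1+h^2/\hat\sigma^2_\theta}$ to preserve the sample variance, and
folds values below 1 back across the boundary. Pseudo-outputs
$y_i^{(b)} = (\theta_i/\theta_i^*)\,y_i$ define a pseudo reference
technology against which every observed DMU is re-scored. On the
efficiency scale the bias estimate is
$\mathrm{mean}_b(1/\theta_i^{(b)}) - 1/\theta_i$ and the corrected score
$2/\theta_i - \mathrm{mean}_b(1/\theta_i^{(b)})$, which always lies below
the raw score in this orientation.

Choices the user should know about:

* `B = 100` resamples is the default, matching the analysis this package
  reproduces; it is small for stable per-DMU intervals, and the package
  warns below 500.
* Per-DMU intervals are percentile intervals of the corrected-score
  bootstrap distribution, clipped to (0,1]. Yearly-mean intervals (the
  figure-style ribbons) are normal-approximation
  $\bar e \pm 1.96\,\mathrm{sd}/\sqrt{n}$ across jurisdictions — the
  published yearly CIs are on the average, and whether they were
  bootstrap-based is not stated, so the simplest convention is used.
* One master seed; per-year streams are derived by fixed offsets, so any
  single year can be re-run in isolation and reproduce exactly.

## Explaining efficiency: the random-forest determinants stage

Bias-corrected efficiency is regressed on the seven contextual variables
plus calendar year (numeric, absorbing secular change) with a
500-tree random forest, 5 candidate variables per split, and repeated
10-fold cross-validation with 3 repeats. All reported fit metrics (MSE,
RMSE, $R^2$, median absolute error) are computed on pooled held-out
predictions, never on the training fit. "MAD" is read as the median
absolute error of CV residuals.

Variable importance follows the perturbation approach: for each variable,
50 bootstrap subsamples are drawn, the variable is permuted within each
subsample, and the change in prediction RMSE against the subsample's own
baseline is recorded; variables are ranked by mean increase. Permuting
(rather than dropping and refitting) is the model-agnostic reading of
"eliminating" a variable and avoids refitting 8 × 50 forests.
Predictions in this stage are evaluated out-of-bag — each row is scored
only by trees that did not train on it. This matters: scored on its own
training rows, a forest assigns visibly positive importance to pure-noise
features (memorized noise splits), violating the basic sanity requirement
that an irrelevant feature's importance be statistically
indistinguishable from zero. Out-of-bag evaluation restores it.

Partial dependence sweeps each variable over 20 grid points spanning its
observed 1st–99th percentile range, averaging predictions over 500
sampled observations (fewer if the panel is smaller). Regional subgroup
analysis refits the same configuration independently within each of the
six socioeconomic regions; regions with fewer rows than the CV fold count
are skipped with a warning.

## Summaries and tests

Yearly and regional summaries report means, SDs and normal-approximation
intervals; growth rates between period means are **truncated toward
zero** at two decimals rather than rounded — the convention that exactly
reproduces published two-decimal rates (66.666… prints as 66.66,
−1.9607… as −1.96). Where the published table derives rates from printed
two-decimal means, `summarize_regions()` does the same from its own
rounded means. The trend test is the two-sided OLS slope test of score on
year and the between-region test is a one-way ANOVA F-test; neither test
is named in the source analysis, so these are deliberately the simplest
conventional choices. Both hold nominal size in the test suite's null
simulations. No multiplicity adjustment is applied across regions.

## The synthetic panel generator

The administrative panel behind the original analysis is not publicly
deposited, so the package generates synthetic panels with the same schema
and known ground truth; every stage is tested against that truth.

* **Technology.** Inputs are drawn from gamma marginals calibrated to the
  2009 administrative means (±20% band asserted in tests); infrastructure
  rates decline mildly over time and the emergency-office rate vanishes
  after 2012 (exercising zero-column handling). The frontier is
  Cobb–Douglas on the infrastructure and human-resource aggregates,
  $g = A\,\mathrm{infra}^{0.30}\mathrm{hr}^{0.45}$, with elasticity sum
  0.75 < 1 so the true technology is strictly VRS and the BCC assumption
  is the correct one.
* **Inefficiency.** $u = m(\mathrm{year})\,[\max(\mathrm{softplus}
  (\beta^\top z) - \log 2,\,0) + |N(0,\sigma_u)|]$, where $z$ are the
  standardized contextual variables. The softplus is centered so that
  zero context effects put every unit exactly on the frontier; the clip
  keeps $u \ge 0$ while preserving monotonicity, so above-median
  contextual disadvantage generates inefficiency and the true Farrell
  distance is exactly $e^{u}$. Effect signs mirror the reported
  determinants (marginalization, indigenous share, demand and inequality
  raise inefficiency; coverage, employment and support reduce it), with
  marginalization largest.
* **Year effects.** $m(\mathrm{year}) = 7.09 - 5.94\,
  e^{-((\mathrm{year}-2016)/5)^2}$, calibrated once so the default
  panel's yearly mean efficiency runs roughly 0.45 → 0.70 → 0.52 with the
  peak in 2016 — the rise-then-decline shape of the published series.
  $\sigma_u = 0.05$ keeps the idiosyncratic share of inefficiency small,
  consistent with the high reported predictability of efficiency from
  context; with this default the end-to-end cross-validated $R^2$ on
  bias-corrected scores clears 0.7 on the default panel.
* **Outputs.** Controlled cases are a jittered ~40% share of treated
  cases (their observed ratio), avoiding the invention of a second
  technology. Contextual variables are independent scaled Beta/Normal/
  gamma draws at the administrative magnitudes, with a systematic
  region-level gradient (more marginalized low-index regions); only the
  marginal moments are calibrated because no cross-correlations are
  published — this independence is a known simplification, and
  `region_gradient = 0` makes regions exchangeable for stability checks.

What the generator does **not** emulate: spatial structure, population
denominators, serial correlation of inputs within a jurisdiction,
cross-correlated context variables, and record-level case extraction.
Passing recovery tests therefore show the estimators work when their
assumptions hold at administrative magnitudes — not that the original
administrative estimates are reproduced.

## Problem sizes, tolerances, degenerate inputs

The test suite runs the full default conditions (242 jurisdictions × 12
years, B = 100) once for the end-to-end check and scaled panels (40–200
jurisdictions) elsewhere; the acceptance script uses the full default
panel for the headline series and a 100-jurisdiction panel for the
importance stage. These sizes are the package's own choices for routine
verification. LP equality assertions use 1e-6, feasibility 1e-9.
Degenerate cases are defined, not accidental: identical DMUs all score 1
with zero bootstrap bias; a zero-variance distance sample has bandwidth
0; a single estimate in a year yields a flagged point interval; a
constant score series has trend p = 1; a constant regression target is
rejected outright.

## Known limitations

* The simplex solver is dense and single-threaded; it is sized for
  hundreds of DMUs, not tens of thousands.
* The homogeneous bootstrap assumes the inefficiency distribution does
  not depend on inputs; no heterogeneous/conditional variant is provided.
* Percentile CIs with B = 100 are noisy; raise B for serious interval
  work.
* Efficiency scores enter the forest as if observed; the two-stage
  sampling noise of estimated scores is not propagated into the
  importance dispersion.
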