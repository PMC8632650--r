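---
title: "Methods: linear-quadratic calibration and dose estimation from TC-stained aberration scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linear-quadratic calibration and dose estimation from TC-stained aberration scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytodose)
```

## Scope and data model

`cytodose` implements the statistical core of dicentric-based biological
dosimetry with telomere/centromere (TC) staining. The unit of
observation is a scored metaphase; a record carries the donor, group,
dose, the centromere count, and one count per aberration class:
dicentrics (`dic`), centric rings (`cring`), acentric rings (`aring`),
acentric fragments with four / two / zero telomere signals (`ace_4tel`,
`ace_2tel`, `ace_0tel`), and telomere deletions (`teldel`). Only
metaphases with exactly 46 centromeres are analyzable — an incomplete
spread could hide aberrations — and `filter_analyzable()` /
`tally_scores()` enforce this before any aggregation.

## DSB accounting

TC staining allows the number of unrepaired or misrepaired double-strand
breaks to be counted with fixed per-class weights: a dicentric or
centric ring, together with the 4-telomere fragment that accompanies a
fusion event, is 2 DSB; a terminal deletion (`ace_2tel`) is 1 DSB; an
interstitial deletion (`ace_0tel`) is 2 DSB; a telomere deletion is
1 DSB.

Two points were genuinely open and are resolved as follows:

* **Excess 4-telomere fragments.** A 4-telomere fragment is normally the
  by-product of a visible dicentric or ring and is absorbed into that
  event's 2 DSB. When a tally contains more `ace_4tel` than
  `dic + cring`, the surplus is scored at 2 DSB each — a fusion whose
  exchange partner was not recovered. Pairing is done at tally level,
  not per cell, because fitting consumes per-dose aggregates anyway and
  tally-level pairing keeps `count_dsb()` additive in the common case.
* **Acentric rings.** They are scored but carry no conventional weight;
  ring formation needs two breaks, so the default weight is 2, exposed
  as `aring_weight` for laboratories that prefer another convention.

## The calibration model

Per-cell yield follows the linear-quadratic form `Y(D) = C + αD + βD²`.
The count of aberrations at dose `D_i` over `n_i` analyzable cells is
modelled as quasi-Poisson with mean `n_i · Y(D_i)`: identity link on the
yield with cells scored as multiplicative exposure, which is exactly the
additive quadratic fitted to counts. `lq_fit()` maximises the Poisson
likelihood by Fisher scoring with:

* **Non-negativity.** `C, α, β ≥ 0` (physical yields). A coefficient
  driven to the boundary is pinned at 0 and the others re-profiled; a
  coefficient sliding geometrically into the boundary is snapped to an
  exact zero when that does not reduce the likelihood, which keeps the
  Fisher weights finite when e.g. zero-dose cells contain no aberrations
  at all.
* **Convergence.** Relative log-likelihood change below `1e-10`
  (`tol`) together with a scaled stationarity check, capped at 100
  iterations (`max_iter`). If no further progress is possible in double
  precision, the point is accepted when the stationarity residual is
  still small; otherwise the fit carries a non-convergence warning.
* **Quasi-Poisson scale.** The covariance of the estimates is the
  inverse Fisher information times the Pearson dispersion
  `X²/df`, floored at `scale_floor = 1` by default so standard errors
  are never anti-conservative. Boundary coefficients contribute zero
  rows/columns to the reported 3×3 `vcov`.
* **Degenerate data.** All-zero counts return `C = α = β = 0` with a
  `degenerate` flag rather than an error; fewer than three distinct
  doses is an error (three parameters need three design points).

Fits accept per-dose aggregates; per-cell records are tallied first (the
Poisson likelihood is identical either way). The fitted object supports
`coef`, `vcov`, `predict` (delta-method yield standard errors from
`v = (1, D, D²)`), `confint`, `residuals`, `simulate`, `plot`,
`summary`; `curve_table()` produces the conventional α ± SE / β ± SE /
α/β / cov(α, β) summary, with α/β rounded to two decimals as customarily
printed.

## Dispersion diagnostics and exact intervals

`dispersion_stats()` reports the dispersion index σ²/ȳ (sample variance,
`N − 1` denominator, matching the statistic's own `N − 1` term) and the
Papworth statistic `u = (σ²/ȳ − 1)·√((N−1)/(2(1−1/X)))`. `u` is reported
as undefined — not as a number — when fewer than two aberrations were
scored. Under Poisson sampling `|u| > 1.96` fires at roughly the nominal
5% rate, which the test suite checks at λ between 0.1 and 1.6 over a
thousand replicates.

`exact_poisson_ci()` gives the Garwood interval
`[½χ²(a/2; 2x), ½χ²(1−a/2; 2x+2)]` (lower endpoint 0 at `x = 0`), which
is conservative by construction: simulated coverage is ≥ 95% at nominal
95%.

## Dose estimation and Merkle bounds

`invert_curve()` solves the quadratic on its physical branch and returns
0 for yields at or below background. `estimate_dose()` combines two
uncertainty sources, both configurable:

* the Garwood interval of the observed count at `conf_count` (default
  95%; `conf_count = 0` degenerates to the observed count, so with a
  zero-width `vcov` the interval collapses onto the point estimate);
* the Wald envelope `Y(D) ± z·SE(D)` of the curve at `conf_curve`
  (default 95%), with `SE(D)` from the fit's variance-covariance matrix.

The lower dose bound is where the upper envelope crosses the count's
lower limit (clamped at 0 when unsolvable); the upper bound is where the
lower envelope crosses the count's upper limit, found by bracketed root
finding on `[0, d_max]` (default 10 Gy). An upper bound that cannot be
bracketed is reported at `d_max` with an `open_upper` flag, and
estimates beyond the calibration range carry an `extrapolated` flag.
Holding both levels at 95% is transparent and conservative — joint
coverage is at least 90% by Bonferroni reasoning, and simulated coverage
at 0.5–4 Gy with 500 cells sits well above that. Whole-body acute
exposure is assumed throughout; partial-body (contaminated-Poisson)
corrections are out of scope.

## Group comparison

Three complementary views, because near-zero backgrounds break the usual
asymptotics:

* `compare_rates()` — the exact conditional test: given the total count,
  the first group's count is binomial with probability proportional to
  its cells scored, so the test stays exact at zero counts (an African
  background of 0 dicentrics in 12,450 cells against 6 in 5,200 gives
  p ≈ 6.5 × 10⁻⁴). Two-sided p by minimum likelihood (default) or tail
  doubling.
* `compare_distributions()` — Kruskal–Wallis on per-cell counts at
  matched doses; since what the "samples" are is a user choice, per-donor
  mean yields can be passed instead for a donor-level comparison.
* `compare_curves()` — a 2-df Wald contrast on `(α, β)` with the pooled
  covariance, for published-coefficient comparisons.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure of a TC-scored calibration
study: for each dose and cell, each class count is drawn with mean
`C + αD + βD²` — Poisson at dispersion 1, gamma-mixed Poisson (negative
binomial, variance `d·λ`) above it. Defaults mirror a typical study:
doses {0, 0.5, 1, 2, 4} Gy and 200 metaphases per dose (two slides of
about 100). `simulate_tally()` is the distribution-identical aggregate
fast path used by the larger simulation suites.

Design choices:

* **Class coupling.** Each dicentric/centric ring is accompanied by
  exactly one 4-telomere fragment, as the scoring rule pairs them
  (`coupling = "independent"` exists for stress testing). This makes the
  DSB closure `total = 2(dic+cring) + ace_2tel + 2·ace_0tel + teldel`
  exact on simulated data.
* **Presets.** The four cohort presets take their dicentric `(α, β)`
  from the shipped reference coefficients exactly; centric rings carry
  the (dicentrics+rings) minus dicentrics surplus, floored at 0; the
  DSB-row surplus beyond `2·(dic+ring)` is split 50/25/25 (in DSB) among
  terminal deletions, interstitial deletions and telomere deletions —
  no class-wise breakdown is published, so the split is a modelling
  choice, exposed as a parameter.
* **Backgrounds.** African-ancestry presets have a dicentric background
  of exactly 0 (none was observed in 12,450 cells), plus a small
  deletion-class background totalling 0.0017 DSB per cell; the Caucasian
  preset uses 6/5,200 dicentrics per cell.
* **Overdispersion.** Presets apply dispersion 1.0 everywhere and 1.3 at
  4 Gy, where mild overdispersion is the empirical norm.
* **Donor frailty.** An optional per-donor lognormal multiplier on
  yields (off by default) for inter-individual studies.

What the generator does *not* emulate: correlations between classes
beyond the fusion pairing, donor-specific repair phenotypes (beyond the
frailty option), scorer variability, and culture/selection effects on
heavily damaged cells. Passing tests therefore demonstrate correctness
of the statistical machinery under the stated model, not validity of the
model for any particular laboratory's data.

## Problem sizes and numerical conventions

The simulation suites use 200 replicate cohorts of 5 × 2,000 cells for
parameter recovery, 500 replicates of 500 cells per dose for Merkle
coverage, and 1,000 replicates for test calibration — sizes at which
Monte-Carlo error is small against the tolerances being checked while
the whole suite stays fast. File output (CSV/JSON) is written at 6
significant digits so identical runs are byte-identical; full precision
is kept in memory. All simulation entry points take an integer seed and
restore the caller's RNG state.

## Known limitations

* Identity-link quasi-Poisson is the field's convention, but yields very
  close to zero put coefficients on the boundary, where Wald intervals
  are approximate (the boundary coefficient's variance is reported as 0).
* Merkle bounds rely on a normal approximation for the curve envelope;
  at very low counts the Garwood side dominates and the approximation is
  immaterial, but for published curves with large coefficient SEs the
  envelope can fail to bracket within `d_max`, reported via `open_upper`.
* The F-ratio convention (rings per dicentric, ~0.05 in healthy European
  donors) is reported as `cring/dic`; the inverse reading exists in the
  literature, so the function documents its orientation explicitly.
* No partial-body, protracted-exposure, or mixed-field corrections.
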