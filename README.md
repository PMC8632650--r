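# cytodose

Cytogenetic biological dosimetry from telomere- and centromere-stained
chromosomal aberration scores.

## What it is for

After an accidental or medical radiation exposure, the absorbed dose can
be estimated from the frequency of unstable chromosomal aberrations in
peripheral blood lymphocytes — dicentric chromosomes above all, the
gold-standard radiation biomarker. Telomere/centromere (TC) staining
resolves every unstable aberration class unambiguously: dicentrics,
centric rings, acentric rings, acentric fragments with four (`ace(+/+)`),
two (`ace(±)`, terminal deletions) or zero (`ace(−/−)`, interstitial
deletions) telomere signals, and telomere deletions. Fixed per-class
weights then convert the visible damage into a count of unrepaired or
misrepaired DNA double-strand breaks (DSB).

`cytodose` is for laboratories running this assay: it takes per-metaphase
or per-dose score tables, builds calibration curves, runs the standard
quality diagnostics, inverts curves into dose estimates with uncertainty,
and compares donor groups. A seeded synthetic-cohort generator makes the
whole pipeline testable without access to scored patient data.

## The model

Per-cell aberration yield follows the linear-quadratic form standard for
low-LET radiation,

    Y(D) = C + αD + βD²,

and the aberration count at dose `D` over `n` scored cells is treated as
quasi-Poisson with mean `n·Y(D)`: Poisson maximum likelihood with the
cells scored as exposure (identity link on the yield), the covariance of
`(C, α, β)` scaled by the Pearson dispersion estimate (floored at 1), and
all three coefficients constrained non-negative, as physical yields are.

Around the fit:

* **Dispersion diagnostics** — the variance-to-mean ratio σ²/ȳ of
  per-cell counts and the Papworth `u = (σ²/ȳ − 1)·√((N−1)/(2(1−1/X)))`;
  `|u| > 1.96` flags departure from Poisson at the 5% level.
* **Exact Poisson (Garwood) intervals** for observed counts, from
  chi-square quantiles.
* **Dose estimation** — the curve is inverted at the observed yield
  (`D = (−α + √(α² + 4β(y−C)))/(2β)`), and Merkle's method intersects the
  Garwood interval of the count with the Wald confidence envelope of the
  curve (from its variance-covariance matrix) to give dose bounds.
* **Group comparison** — exact conditional (binomial) tests of two
  Poisson rates, Kruskal–Wallis tests on per-cell distributions, and Wald
  contrasts on fitted `(α, β)`.

Reference coefficients for four healthy-donor cohorts (African ancestry
living in Africa — Senegal only and all-country; African ancestry living
in Europe; Caucasians living in Europe) ship with the package
(`reference_curves()`) and drive the simulator presets.

## Worked example

```r
library(cytodose)

## a synthetic calibration cohort: 1,000 metaphases per dose at
## 0/0.5/1/2/4 Gy, dicentric yields at the Senegal-in-Africa preset
spec   <- cohort_preset("senegal_africa", cells_per_dose = 1000, seed = 7)
scores <- simulate_cohort(spec)
tal    <- tally_scores(scores)

fit <- lq_fit(tal, endpoint = "dicentrics")
summary(fit)
#> Quasi-Poisson linear-quadratic calibration (dicentrics)
#>
#>       Estimate Std. Error z value Pr(>|z|)
#> C     0.000000   0.000000       -        -
#> alpha 0.165251   0.013519   12.22   <2e-16 ***
#> beta  0.061958   0.004789   12.94   <2e-16 ***
#>
#> Dispersion scale: 1.0000 (Pearson estimate 0.1179)
#> alpha/beta: 2.67 Gy;  cov(alpha, beta): -5.67e-05
#> Coefficients pinned at zero: C
```

The fitted α = 0.165 ± 0.014 and β = 0.0620 ± 0.0048 recover the
generating values (0.168, 0.061) well within one standard error; the
zero-dose cells contained no dicentrics, so the background `C` sits on
its physical boundary at 0.

```r
dispersion_stats(scores$dic[scores$dose_gy == 4])
#> Per-cell count dispersion
#>   N = 1000 cells, 1649 aberrations; mean 1.649, variance 1.95
#>   dispersion index 1.182, u = 4.077 (departs from Poisson at 5%)
```

The 4 Gy preset deliberately injects mild overdispersion (1.3), and the
u statistic flags it; at all lower doses the counts are Poisson.

```r
estimate_dose(fit, observed_count = 165, n_cells = 100)
#> Dose estimate (dicentrics): 3.996 Gy  [3.523, 4.540]
#>   from 165 aberrations in 100 cells (yield 1.65/cell); count CI 95%, curve envelope 95%

compare_rates(6, 5200, 0, 12450, group_ids = c("caucasian", "african"))
#> rate_test: statistic = 6, p = 0.000654
#>   groups: caucasian vs african
```

165 dicentrics in 100 cells (yield 1.65/cell) points at essentially
4 Gy, with 95/95 Merkle bounds of 3.5–4.5 Gy. The rate test compares the
spontaneous backgrounds — 6 dicentrics in 5,200 Caucasian metaphases
against 0 in 12,450 African metaphases — exactly, despite the zero count.

A thin command-line wrapper over the same functions lives at
`inst/cli/cytodose.R` (subcommands `simulate`, `calibrate`, `estimate`,
`compare`, `dsb`).

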