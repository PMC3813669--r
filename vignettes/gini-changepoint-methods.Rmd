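---
title: "Measuring and testing trends in geographic provider inequality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and testing trends in geographic provider inequality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ginitrend)
```

`ginitrend` quantifies how unevenly a provider workforce (physicians,
pediatricians) is distributed across the spatial units of a region, and
tests whether that inequality's time trend changed at a known intervention
date. This vignette documents the methods, the choices behind them, and
what the synthetic validation does and does not establish.

## The population-weighted Gini

For one region in one survey year, each unit (municipality) contributes a
denominator population $p_i$ and a provider count $q_i$. Units are sorted
by ascending ratio $r_i = q_i/p_i$ (stable for ties; the value is invariant
to tie order) and the Lorenz curve accumulates population shares on the
x-axis and provider shares on the y-axis. The Gini is computed by the
trapezoid rule

$$G = 1 - \sum_k (x_k - x_{k-1})(y_k + y_{k-1}),$$

clamped to $[0, 1)$ against floating-point drift. Because the empirical
Lorenz curve is piecewise linear, this is algebraically identical to the
population-weighted pairwise mean difference
$G = \sum_{i,j} w_i w_j |r_i - r_j| / (2\mu)$ with $w_i$ the population
shares and $\mu$ the overall rate. Both routes are implemented
(`gini_from_lorenz()`, `gini_pairwise()`) and the test suite holds them to
within $10^{-12}$ of each other on random instances; the pairwise form is
the permanent cross-check of the production trapezoid path.

Conventions for degenerate inputs:

* **Zero-provider units are included** with ratio 0 — they form the flat
  initial Lorenz segment. Excluding them would understate inequality and
  break the interpretation of the x-axis as the cumulative population
  share. This mirrors how areas with residents but no physicians still
  count as under-served population.
* **Zero-population units are excluded** (with a warning): their ratio is
  undefined. They remain in storage and are flagged by `validate_panel()`.
* **Region-years with zero total providers** have an undefined Lorenz
  curve; `gini_panel()` emits them as missing (never as 0) and the
  regression drops them listwise with a logged count.
* Pediatrician inequality always uses the under-15 child population as the
  denominator; physician inequality uses the total population.

The optional small-sample correction multiplies a region-year's Gini by
$n/(n-1)$ ($n$ = number of units, $n \ge 2$). It leaves regression *slope*
contrasts nearly unchanged when $n$ is constant over time, which is why the
harmonized-boundary crosswalk matters: `apply_crosswalk()` merges
pre-reform units onto a fixed (many-to-one, never region-crossing) unit
set, so $n$ and the unit boundaries are constant across waves. Merging can
only hide within-merge inequality, so a merged Gini never exceeds the
original — a property the tests check against the pairwise oracle.

## The fixed-knot change-point regression

The region-wave Gini panel $Y_{ij}$ is modelled as

$$E(Y_{ij}) = \beta_0 + \beta_1 t_{ij} + \beta_2 z_{ij}
  + \beta_3 z_{ij} t_{ij},$$

with $z = 1$ for waves at or after the knot year. The knot year itself
belongs to the post-period: an intervention taking effect early in the
knot year is already reflected in a survey conducted at the end of it. The
pre-period slope is $\beta_1$, the post-period slope $\beta_1 + \beta_3$,
and $\beta_3$ — the slope change — is the effect estimate; `slopes()`
returns the pair.

Choices a user should be aware of:

* **Time coding.** The time scale is not canonical for biennial surveys.
  The default `wave-index` counts surveys (one unit = one wave);
  `calendar-offset` counts years. $\beta_1$ and $\beta_3$ scale by the
  factor 2 between them, so every fit object and report embeds its coding
  descriptor. Shifting the time origin changes $\beta_0, \beta_2$ but not
  $\beta_1, \beta_3$, their p-values, or fitted values (tested).
* **Estimator.** Pooled OLS over all region-wave rows, one row per
  region-wave, regions equally weighted. This matches the single-SE-per-
  coefficient layout of published change-point tables. No mixed-effects
  structure is fitted; when within-region correlation is a concern,
  `se_type = "cluster"` gives CR1 cluster-robust standard errors by region
  with a $t_{G-1}$ reference distribution. The two options share identical
  point estimates.
* **Inference.** Two-sided p-values from the $t$ distribution with
  residual df (conventional) or $G-1$ df (cluster); $\alpha = 0.05$ is the
  conventional significance threshold used in the stratified pattern
  checks.
* The design must span both sides of the knot with at least four distinct
  rows; otherwise the fit aborts with a rank-deficiency error rather than
  silently dropping terms.

Stratified analyses split regions into `urban` and `other` by a
`strat_scheme` and fit each stratum independently. Three Japanese
prefecture classifications are embedded as fixed lists (OECD regional
typology, 13 urban; metropolitan-area codes, 14; population density
≥ 1000/km², 7 — matching is case-insensitive), plus custom lists from a
one-id-per-line file. The built-ins are fixed data, not derived: computing
typologies from commuting or density data is out of scope.

## The synthetic generator

Registry microdata underlying analyses like this are generally not
redistributable, so validation rests on a generator whose defaults *are*
the study conditions the package targets: 47 regions named after the
prefectures (so the built-in schemes apply), 37 units per region (≈ 1,750
units nationally), eight biennial waves 1996–2010, knot 2004, baseline
within-region Gini 0.30, pre-slope −0.003/wave, slope change +0.006/wave,
and wave-level Gaussian noise of sd 0.01 on the Gini scale. The baseline
and slope magnitudes sit where intra-prefectural physician Gini panels
empirically sit (≈ 0.28–0.35, with per-wave movements of a few 0.001);
the base rates (184.4 physicians per 100,000 population, 82.5
pediatricians per 100,000 children) and the 0.15 child fraction match the
published national totals shipped in `inst/extdata/`.

Mechanism, per region: unit populations are drawn once from a lognormal
(meanlog 10, sdlog 1 — median ≈ 22,000 with a heavy right tail, the shape
of municipality populations) and held fixed over waves, as are unit-level
standard-normal shocks $Z_i$. For wave $\tau$ (0-based index) the target
Gini is

$$G_{r\tau} = \mathrm{clip}\big(G_{0r} + s_{1r}\tau
  + \Delta_r(\tau - \tau_k)\,\mathbf{1}[\tau \ge \tau_k]
  + \varepsilon_{r\tau}\big),$$

clipped to $[0, 0.95]$ (never binding at the default magnitudes), and unit
ratios are $\text{base rate} \times \exp(\sigma Z_i - \sigma^2/2)$. The
lognormal family is used because its Gini has the closed form
$G = 2\Phi(\sigma/\sqrt2) - 1$ (`expected_gini_lognormal()`,
`sigma_for_gini()`), giving an analytic generator↔estimator link. Note the
trajectory is written so that the slope simply changes at the knot; fitted
through the change-point design this yields $\beta_3 = \Delta$ and
$\beta_2 = -\Delta\tau_k$, so the generator's $\Delta$ is exactly the
estimand.

**Calibration.** With finitely many units the realized weighted Gini of a
draw deviates from the lognormal limit by a region-specific offset
(because populations and $Z_i$ are fixed across waves, the offset persists
over time). Left in place, that offset would act as an unmodelled region
random effect and distort conventional-SE inference in validation studies.
The generator therefore, by default (`calibrate = TRUE`), solves for
$\sigma$ per region-wave by monotone root-finding so that the realized
population-weighted Gini of the drawn units equals the target exactly
(residual ≈ $10^{-12}$). The panel-level error term is then precisely the
injected iid $\varepsilon_{r\tau}$ — the assumption the OLS validation is
meant to test. `calibrate = FALSE` exposes the raw analytic link; at 2,000
units per region the realized Gini sits within about ±0.01 of target (the
finite-sample error of a weighted Gini with heavy-tailed weights; the
convergence test uses this scale), shrinking like $1/\sqrt{n}$.

Counts are real-valued expectations in `deterministic` mode (the default,
sharpest for recovery studies) or Poisson draws around them
(`poisson` mode, converging to deterministic as rates grow). Populations
are constant over waves by default for test sharpness — real child
populations declined ≈ 13% over 1996–2010, a drift the generator does not
model. Other unmodelled features of real registry data: spatial
correlation between neighbouring units, physician migration dynamics,
part-time/headcount discrepancies, and municipal mergers (the generator
emits already-harmonized units; crosswalk behaviour is tested separately).
Passing validation therefore shows the estimator chain is correct under
its own assumptions, not that those assumptions hold in any particular
registry.

`recovery_experiment()` runs generate → `gini_panel()` →
`fit_changepoint()` over independent sub-seeded replicates and summarizes
$\hat\beta_3$: bias, empirical 95% CI coverage, and rejection rate of
$H_0\!: \beta_3 = 0$. At the default conditions the suite requires
$|\,\overline{\hat\beta_3} - 0.006| < 5\times10^{-4}$ over 200 replicates
with coverage in $[0.90, 0.98]$; with $\Delta = 0$, rejection within
binomial Monte-Carlo error of 5% over 400; and when only non-urban regions
carry the break, the urban/other rejection pattern must appear in ≥ 90% of
replicates. Problem sizes (200–400 replicates at the 47 × 37 × 8 scale)
keep each study under a couple of minutes on one CPU while leaving the
Monte-Carlo error well inside the tolerance being asserted.

## Numerical conventions

* Reported per-capita rates round **half-up** at one decimal
  (`per_capita_rate()`), matching the convention of published workforce
  tables; unrounded values are available with `reporting = FALSE`.
* Gini values are clamped to $[0, 1)$ after cumulative summation in double
  precision; calibration root-finding uses tolerance $10^{-10}$.
* Sorting by ratio uses R's stable radix order, so equal-ratio units keep
  input order (and provably cannot affect the value).
* Sub-seeds for replicates are drawn once from the configured seed, so a
  `synthetic_config` seed fully determines every experiment byte-for-byte.
* CSV writers emit a fixed column order with LF endings; pipeline
  artifacts carry a config hash and seed in comment lines that the
  package's readers skip.

## Limitations

* The change-point model assumes a linear trend on each side of a *known*
  knot; knot search, autocorrelation-robust inference, and mixed-effects
  pooling are out of scope.
* The regression weights regions equally; population-weighted pooling
  would answer a different (person-weighted) question.
* The `n/(n-1)` adjustment corrects scale, not the sampling distribution;
  no bootstrap CIs for individual Gini values are provided.
* Built-in urban/rural lists apply to the 47 Japanese prefectures only;
  other geographies need custom schemes.
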