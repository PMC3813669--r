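# ginitrend

Geographic inequality in a provider workforce — physicians, pediatricians,
or any headcount distributed over spatial units — is commonly summarized by
a population-weighted Gini coefficient: municipalities are ranked by their
provider-to-population ratio, the Lorenz curve plots the cumulative share
of providers (y) against the cumulative share of the population they serve
(x), and the Gini is twice the area between the curve and the diagonal
(0 = perfectly even, values near 1 = extreme concentration).

`ginitrend` packages that analysis end to end for panel data — many regions
(e.g. the 47 Japanese prefectures), each containing many spatial units
(municipalities), observed over repeated survey waves — and asks the
interrupted-time-series question: **did the inequality trend change after a
policy intervention?** It is aimed at health-services and health-workforce
researchers working with registry-style counts.

## The model

For each region *i* and wave *j*, the within-region Gini `Y_ij` is
regressed on a fixed-knot linear change-point (segmented) design:

```
E(Y_ij) = β0 + β1·t_ij + β2·z_ij + β3·z_ij·t_ij
```

where `t` is time (by default the survey-wave index), and `z = 1` for waves
at or after the knot year. The mean response is `β0 + β1·t` before the knot
and `(β0 + β2) + (β1 + β3)·t` after, so **β3 is the pre-vs-post difference
in slope** — the policy-effect estimate. Fits are pooled OLS over all
region-wave rows, with conventional or cluster-robust (by region) standard
errors, and can be stratified by built-in urban/rural classifications of
the Japanese prefectures (OECD regional typology, metropolitan-area codes,
population density) or by a custom list.

The Gini itself is computed two independent ways — the trapezoid Lorenz
area rule (the implementation) and the population-weighted pairwise
mean-difference (a cross-check oracle, algebraically identical for
piecewise-linear Lorenz curves) — and an optional `n/(n−1)` small-sample
adjustment is provided. A boundary crosswalk merges pre-reform
municipalities onto fixed harmonized boundaries so the unit set is constant
over time.

Because municipality-level registry data are typically not redistributable,
the package includes a first-class synthetic generator: heavy-tailed unit
populations, lognormal provider-ratio shocks whose shape is linked to a
target Gini (`G = 2Φ(σ/√2) − 1`, solved exactly per region-wave by
calibration), a configurable trajectory with slope break, and a
parameter-recovery harness (bias, CI coverage, type-I error).

## Worked example

Simulate a study-scale panel (47 prefectures × 37 municipalities, eight
biennial waves 1996–2010, baseline Gini 0.30, improving pre-trend, slope
break +0.006/wave at 2004, wave noise 0.01), then estimate the break:

```r
library(ginitrend)

cfg   <- synthetic_config(seed = 42)
panel <- generate_panel(cfg)              # 13,912 unit-year records
gp    <- gini_panel(panel, "physicians")  # 47 x 8 region-wave Gini values
fit   <- fit_changepoint(gp, knot_year = 2004)
fit
#> <changepoint_fit>  knot = 2004  coding = wave-index  SE = conventional
#>   n_obs = 376  regions = 47
#>   term     label  estimate        se   p_value
#>  beta0 intercept  0.299871 0.0012462 0.000e+00
#>  beta1      year -0.003027 0.0006661 7.469e-06
#>  beta2         z -0.022928 0.0039408 1.284e-08
#>  beta3    z:year  0.005962 0.0009420 7.088e-10
#>   slope pre = -0.003027, post = 0.002936 (per wave-index unit)
```

The Gini trend was falling by about 0.0030 per wave before 2004 and rising
by about 0.0029 per wave afterwards; the slope change `β3 = 0.0060`
(p ≈ 7e-10) recovers the injected +0.006. Stratified fits localize the
break: with the OECD urban list,
`stratified_fits(gp, "oecd", 2004)` reports β3 for each stratum
separately. Per-capita reporting matches published conventions:

```r
per_capita_rate(230297, 124.9e6)  # physicians per 100,000, one decimal
#> [1] 184.4
```

A thin CLI over the same functions lives in `inst/cli/ginitrend.R`
(subcommands `simulate`, `gini`, `fit`, `stratify`, `run-all`), and
`run_pipeline()` orchestrates validate → crosswalk → Gini panels → fit →
stratified fits → mean series with provenance-stamped CSV/JSON artifacts.

## Documentation

The methods vignette (`vignettes/gini-changepoint-methods.Rmd`) describes
the estimators, the generator design and its calibration link, default
parameter choices, numerical conventions, and known limitations.
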