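---
title: "Methods: mortality estimation, projection and LTCI fund simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mortality estimation, projection and LTCI fund simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltcisim)
```

`ltcisim` chains five models: annual life-table estimation from sparse
census anchors, Lee–Carter mortality projection with rotation,
cohort-component population projection, disability-prevalence demand
scenarios, and a dynamic-financing insurance-fund ledger. This vignette
documents the modelling assumptions, the tunable parameters and their
defaults, the numerical choices, and what the synthetic test conditions
do and do not demonstrate.

## Life-table engine

All mortality quantities flow through one abridged/single-age life-table
constructor (`lifetable`). Closed intervals convert central death rates
with q = n·m/(1 + (n − a)·m); the open interval uses L = l/m. The only
separation factor that materially moves life expectancy is the infant
one, so a(0) follows an Andreev–Kingkade-style piecewise-linear function
of the infant death rate by sex, and every other closed interval uses
n/2. The radix is 100,000; the open interval sits at 100+ for
census-style inputs and 110+ on the coefficient grid of the
log-quadratic system. Closed-interval death probabilities are capped at
1 − 10⁻⁹ so survivorship stays strictly positive, which keeps log-scale
graduation defined even under extreme projected old-age rates.

Graduation to single ages interpolates log l(x) with a monotone cubic
(PCHIP) through the abridged boundaries. PCHIP (Fritsch–Carlson) is
implemented in the package and cross-checked in the test suite against
an independent implementation to 10⁻¹⁰; it passes through knots exactly
and cannot overshoot, which is what keeps interpolated probabilities
inside [0, 1] without clamping. Graduation preserves e₀ to within about
0.1 years on smooth schedules.

## Three-parameter log-quadratic estimation

Each year's table derives from three parameters: ₅q₀ (given annually),
₄₅q₁₅ and ₁₅q₆₀ (anchored at knots, interpolated annually with PCHIP).
The adjustment factor k is solved by bisection on [−10, 10] to 10⁻⁸ on
the probability scale; an objective value whose survivorship collapses
before age 60 is treated as ₄₅q₁₅ = 1, which keeps the bracket valid at
extreme k. The old-age intercept shift uses the cumulative-hazard ratio
closed form; because the closed form is exact only under
piecewise-exponential survival, it is iterated to convergence (the
`refine` flag) so the rebuilt table hits ₁₅q₆₀ to 10⁻⁹. The shift
deliberately creates a kink at age 60 — it is piecewise by construction
and no smoothing is applied.

Old-age anchors average a model-implied and an empirical estimate with
equal weights. At census years the empirical estimate is the census
life table's ₁₅q₆₀. At intercensal midpoints it comes from cohort
survival of the census blocks aged 60–74 followed to 70–84 ten years
later. Converting that block survival to a period ₁₅q₆₀ is a genuinely
open design point: a constant-hazard power rule (1 − S^(15/10))
overstates old-age mortality by 35–60% on stationary test populations,
because the hazard roughly doubles across the fifteen-year span. The
package instead fits a two-parameter Gompertz hazard (level and slope)
to the three group survival ratios and integrates the fitted hazard
over ages 60–75. The fit is a Nelder–Mead minimisation of squared log
differences; when the observed ratios are age-flat the fit collapses to
its constant-hazard limit, so the simpler rule is nested. On stationary
populations built from known tables the recovery error is about 1–2%.

### Coefficient schedule

The (a, b, c, v) schedule is shipped as a CSV
(`inst/extdata/logquad_coefs_synthetic.csv`) in the standard published
layout (sex × age groups 0, 1, 5, …, 110+), and any file in that layout
can be substituted. The bundled schedule is synthetic: it is fitted by
`fit_logquad_coefs` to a deterministic Gompertz–Makeham family spanning
child-mortality levels 0.0015–0.20 and a seven-level adult-mortality
spread, by regressing ln m(x) on ln ₅q₀ and its square and taking the
leading singular vector of the residuals as the k-loading. Fitting the
schedule from a generated family rather than shipping a published table
keeps the package self-contained and lets recovery tests compare
against the exact generating truth; the closure error (table-implied
₅q₀ versus requested) is below 0.7% across the range, within the 1%
closure tolerance the estimation assumes.

## Lee–Carter with rotation

`fit_lc` performs the classic SVD decomposition (β normalised to sum 1,
κ to sum 0). Because the fitting inputs here are model-based life
tables rather than raw death counts, the second stage re-solves each
κ(t) so the implied table reproduces that year's e₀ (`match_e0`,
default on); the solved κ are re-centred with the mean absorbed into α,
which preserves the fit exactly while keeping the normalisation. Drift
is the endpoint estimator (κ_T − κ_1)/(T − 1) and σ the standard
deviation of increments about it. One consequence worth knowing: on
smoothly interpolated histories, σ reflects curvature of the e₀ path
more than sampling noise, so predictive intervals vary with the
generator seed.

Projection simulates κ as a random walk with drift. Drift-estimation
uncertainty (a normal draw with s.d. σ/√(T−1) per trajectory) is
included by default and can be toggled; with both noise sources off the
interval collapses, which the tests use as a degenerate check. The age
loading applied to each year's increment is the rotated blend
(1 − w)β + w·β_ultimate, renormalised. The ultimate loading averages β
over ages 15–64, tapers linearly above 65 to a 5% floor at the oldest
age, and renormalises; the weight w rises from 0 at e₀ = 80 to 1 at
e₀ = 102 with smoothness power p = 0.5 (all exposed in
`rotation_params`). w is driven by the deterministic mean e₀ path
rather than per-trajectory e₀, keeping trajectories exchangeable.
Applying the loading to increments (rather than to κ levels) avoids
artifacts when κ changes sign. Rates are anchored at the fitted 2020
table (jump-off bias adjustment on by default in the sense that the
jump-off equals the estimated 2020 table).

Scenario surfaces for the population projection use per-year quantile
paths of the simulated κ: since e₀ is monotone decreasing in κ, the
2.5/97.5 percentile κ paths map to the upper/lower 95% life-expectancy
scenarios. Default 1000 trajectories; a run below 100 is flagged in the
result object rather than refused.

## Cohort-component projection

Populations advance on single ages 0–100+ with survival ratios
L(x+1)/L(x); the last closed age and the open group advance together
with the T-ratio convention. Births apply the year's TFR to an
age-specific shape over ages 15–49 (a discretised normal peaking at 29,
a late-peaking schedule typical of contemporary East Asian populations;
replaceable), split 1.05 males per female, and survive to age 0 with
L(0)/l(0). Net migration is added at the end of each interval — the
simplest placement consistent with an additive migration term — scaled
by a taper that declines linearly from 1 at 2020 to 0 at 2045
(migration equilibrium) and stays 0 after.

The base migration schedule comes from the census survival ratio
method: expected survivors of each five-year cohort between the last
two censuses minus observed counts, spread uniformly over the decade
and over single ages around the cohort's mid-decade age. Cohorts born
between the censuses and cohorts ending in the open group are left at
zero — the recovery tests therefore only assert accuracy at working
ages. The TFR path starts at 1.04 in 2020 and follows a saturating
multiplier path toward roughly 1.4 by 2080, standing in for a published
country-level recovery scenario; it is a plain year→multiplier table
and fully replaceable.

## Disability demand

Severity counts items with difficulty among six activities of daily
living: 0 none, 1–2 mild, 3–4 moderate, ≥5 severe. Prevalence is
tabulated by sex and 5-year age group (60–64 … 100+); any empty cell is
an error by default because demand needs every cell. Scenarios scale
every cell by (1 + r)^(year − 2020) with r = ±0.008 or 0, capped at 1.
The scenario base year 2020 is the one consistent with the bundled
worked-example table for 2030–2080; that table's first row (2023) is
not consistent with any single base year and is excluded from the
worked-example checks. Counts are reported in thousands, rounded half
away from zero, with unrounded values carried alongside; the
high/medium count ratio equals the scenario factor exactly until the
oldest cells hit the probability cap (far-horizon high scenario), after
which it bounds it from below.

## Fund model

Annual expenditure is the share-weighted blend of four service costs —
home-based daily care 1200, institutional 2100, home-based
daily-and-medical and nursing-hospital care both 1680 CNY/month in 2024
— inflated at 2.25%/year, times the severely disabled count. Shares
follow the 90/3/7 elder-care mix, with the final 7% split evenly
between the two equally priced medical-care services (the split is
immaterial at equal cost). Premium income is 90 CNY per contributor
grown at (1 + λ) from base year 2023 (first grown premium 2024; the
anchor is configurable since published accounts mix 2022–2024 anchors),
times the population aged 20+ times a participation rate (default 1).
The accumulated balance compounds at 2.5% interest exactly by the
recursion A_t = A_{t−1}(1 + γ) + C_t from zero. Years before the cost
base year deflate by the same geometric rate rather than erroring, so
ledgers may start in 2023 with 2024-quoted costs. All currency is
nominal CNY; no discounting beyond fund interest.

`min_sustainable_growth` scans λ over [0, 0.10] in steps of 0.0005 (the
granularity at which rates like 4.20% or 5.25% are expressible) for the
smallest value keeping the accumulated balance non-negative through
2080, then verifies the result by re-running at λ* and at λ* − step.
Accumulated balance is non-decreasing in λ at every year, so the grid
scan is exact.

## Synthetic study conditions

The generator (`synth_config`, `generate_*`) emulates the statistical
structure of the pipeline's inputs:

- **Censuses** at 1990/2000/2010/2020 with life expectancy rising
  roughly 68→80 (men) and 72→85 (women) and child mortality falling an
  order of magnitude, from Gompertz–Makeham-with-childhood schedules
  whose (₅q₀, e₀) hit the targets exactly. Pyramids follow survivorship
  discounted by past growth with a baby-boom bulge centred at age 45 in
  2020, so the 60+ population peaks in the late 2050s and then declines
  — the aging dynamic the projection stage must reproduce. Ages 70+ are
  made cohort-consistent between censuses (old ages closed to
  migration) so intercensal survival is well defined. Death counts are
  Poisson draws around population × rate. Old-age mortality improvement
  is damped relative to mid-age improvement (an exponent taper on the
  adult level factor), reproducing the decelerating e₀ gains of
  low-mortality populations.
- **Child mortality**: PCHIP of the census ₅q₀ targets on the log
  scale with 1% lognormal noise, anchored at census years.
- **Disability survey** (default n = 50,000, large enough that
  binomial noise sits below the scenario effects): six independent
  item flags per person with a per-item probability that is
  quadratic-logistic in age with a +0.15 logit female excess,
  calibrated so severe prevalence runs from ~0.5% at 60–64 to over 25%
  at 95+. The generating cell probabilities are returned for recovery
  tests.

Every generator is a pure function of (config, seed). The worked-example
demand table bundled in `table1_fixture` is a frozen reference for the
scenario-factor identities only.

What passing tests show — and do not. The generative tests demonstrate
that each stage recovers the structure it assumes (e₀ within 0.3 years
at census anchors, prevalence within binomial error, λ* equal to a
brute-force scan) and that the chain's qualitative dynamics (rising e₀,
a 60+ peak and decline, an ordered and attainable λ*) emerge from the
inputs. They do not validate the models against any real population:
real censuses have age heaping and differential undercount, real
disability items are correlated within person, migration is not
age-smooth, and real old-age mortality improvement need not follow the
damped pattern generated here. Magnitudes such as the projected e₀ in
2080 or λ* are properties of the synthetic world, not estimates for any
province.

## Problem sizes and numerical settings

Default runs use 1000 projection trajectories (tests use 200–300), a
31-year fitting window, a 2080 horizon, and the 201-point λ grid;
bisection/fixed-point tolerances are 10⁻⁸–10⁻⁹ on probabilities, and
the Gompertz survival fit uses Nelder–Mead with reltol 10⁻¹⁴. The full
synthetic pipeline at default sizes runs in well under a minute on one
core.

## Known limitations

- Only ADL-based disability is modelled; cognitive, perceptual and
  communication dimensions are out of scope.
- Sexes are projected independently (no coherent two-sex forecast); no
  cohort effects or Lee–Carter variants beyond rotation.
- The fund model covers expenditure and premium income only — no
  operating costs, financing-structure split, or reserve funds.
- The census survival ratio method attributes all residuals to
  migration; with noisy censuses it absorbs coverage error too.
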