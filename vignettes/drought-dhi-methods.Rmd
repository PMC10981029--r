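---
title: "Methods: Dynamic Habitat Indices for forest drought assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Dynamic Habitat Indices for forest drought assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in **droughtDHI**, the
assumptions behind them, the parameters that matter, and the choices made
where the methodology left room for interpretation. It states no result
that the package's tests and acceptance script do not themselves compute.

## The DHI model and its assumptions

A pixel's annual phenology is summarised from its within-year
productivity series $p_t$ ($t = 1..n$, here $n = 36$ ten-day NDVI
composites):

$$\mathrm{DHI_{Cum}} = \sum_t p_t, \qquad
  \mathrm{DHI_{Min}} = \min_t p_t, \qquad
  \mathrm{DHI_{Var}} = \sigma(p_t) / \mu(p_t).$$

The components assume that NDVI is a usable productivity proxy over the
target land cover (evergreen coniferous forest), that 36 composites
sample the phenology densely enough for a sum/min/CV to be stable, and —
for the coefficient of variation — that the mean is positive. The
implementation enforces the last point: `DHI_Var` is masked where the
pixel's mean productivity is not positive (water, snow, or senescent
surfaces can push NDVI means to zero or below, where a CV is
meaningless).

Numerical conventions, chosen once and tested:

* $\sigma$ is the **sample** standard deviation ($n-1$ denominator): one
  year's 36 composites are a sample of the continuous phenology, not the
  population. The same convention is reused for the "variation" aggregate
  of every climate variable so that the two families of predictors are
  comparable.
* **Gaps.** Components are computed over the valid composites only, with
  `DHI_Cum` rescaled by $n_{total}/n_{valid}$ so gap-affected pixels stay
  on the same scale. Pixels whose valid fraction falls below
  `min_valid_fraction` (default 0.75) or with fewer than two valid
  composites are masked rather than guessed.
* The **long-term layer** of each component is the element-wise *median*
  over the years, defined where at least half the years are valid. A
  median over four years equals the mean of the two central values and is
  robust to one extreme drought year.
* The false-colour merge maps cumulative productivity to red, minimum
  cover to green and seasonality to blue, each min–max stretched over the
  valid pixels to [0, 255]; a degenerate (constant) layer maps to 0.

## Aridity and zonation

The monthly de Martonne index $\mathrm{dMI} = P/(T + 10)$ uses the
precipitation and temperature grids as supplied — here the monthly mean
of daily *minimum* air temperature, following the data actually used for
this analysis even though the classical index is defined on mean
temperature. Cells with $T \le -10\,°C$ (non-positive denominator) are
masked with a counted warning, never returned as infinities.

"Accumulated drought" is the **sum of monthly dMI over the full study
period**; an alternative reading (dMI of summed precipitation and mean
temperature) differs only by a scale factor under stationary seasonality
but is not the implemented default. The four zones come from **equal-width
intervals** of accumulated dMI between the masked minimum and maximum,
computed over the coniferous-forest mask (configurable to the full
extent). Intervals are half-open with the top class closed,
$[\min, b_1), [b_1, b_2), [b_2, b_3), [b_3, \max]$, so a value exactly on
a break belongs to the upper (wetter) class; a constant field is an error
because no interval width exists.

## Trends and their classification

Theil–Sen is the median of all pairwise slopes
$(y_j - y_i)/(t_j - t_i)$ over a pixel's valid years; with four annual
values that is six pairs. It is exact on linear series and unaffected by
a single outlier from five years on. The OLS alternative first smooths
each annual layer with a square moving-window mean (default 3×3, the
window the method leaves unspecified; edge pixels average what is in
reach) and then fits a per-pixel least-squares slope.

The "considerable trend" rule applies a **two-sided 20 % percentile
threshold with a sign guard**: pixels at or below the 20th percentile of
the masked slope distribution *and* truly decreasing are negative; at or
above the 80th percentile *and* increasing, positive; everything else
indifferent. Two-sidedness is the only reading that yields both a
negative and a positive "considerable" class from one threshold; the sign
guard prevents an all-positive slope field from producing a spurious
negative class. Percentiles are computed per component over the forest
mask only. Zonal summaries report positive/negative pixel counts and
their ratio per aridity zone for three strata (all, damaged,
non-damaged); a zone with zero negative pixels yields an `NA` ratio
flagged undefined — never infinity — and an empty stratum-zone cell is
flagged as such.

## Group statistics

Damaged vs non-damaged comparisons use classical one-way ANOVA, with
Shapiro–Wilk, Bartlett and Q-Q diagnostics returned for inspection (no
automatic accept/reject; failures are counted in the run manifest).
Pairwise contrasts use Tukey–Kramer simultaneous intervals, which remain
valid for unbalanced groups — group sizes are whatever the damage mask
produces. Between-year contrasts reuse the same machinery with calendar
years as groups, which is how a drought step (2019 vs 2017) or a recovery
(2020 vs 2019) is assessed. The sampling unit is the pixel; spatial
thinning (below) is the defence against pseudo-replication.

## The health model

The damage label is modelled as
$p(X) = e^{\beta_0 + \sum_i \beta_i X_i} / (1 + e^{\beta_0 + \sum_i \beta_i X_i})$
on **16 candidate predictors**: the three long-term DHI components, the
cumulative/minimum/variation aggregates of precipitation, temperature,
sunshine duration and monthly dMI, and elevation. The assembly order is:

1. **Spatial thinning** (default 600 m minimum distance, i.e. two
   analysis pixels): greedy removal of the most-crowded sample with
   seeded random tie-breaks, until no pair violates the distance.
2. **Correlation filter** (|Pearson r| > 0.8): of the worst pair, the
   member with the larger mean absolute correlation to all other
   predictors is dropped; ties break alphabetically, making the filter
   deterministic.
3. **VIF filter** (> 5): $VIF_j = 1/(1 - R^2_j)$ from auxiliary
   regressions, removing the largest until all pass. Perfect collinearity
   yields an infinite VIF and is handled by removal, not an error. A lone
   predictor has VIF 1 by definition and is retained.
4. **Fit.** Predictors are standardized for the IRLS iterations and the
   coefficients and covariance are mapped back to the raw scale by the
   exact affine transform, so reported estimates and standard errors
   equal a direct raw-scale fit while keeping the optimisation
   well-conditioned. Perfect separation and non-convergence are detected
   and recorded in the result rather than silently warned away. Constant
   predictors are dropped from the optimisation and reported with a zero
   coefficient.

The filters are applied correlation-first: the correlation rule is the
cheaper, pairwise criterion and the VIF step then resolves the remaining
multivariate redundancy. McFadden's $R^2 = 1 - LL_{fit}/LL_{null}$ is
exactly 0 for an intercept-only model and approaches 1 under separation.
Variable importance is the absolute Wald $z$ statistic — the convention
of the standard GLM importance tooling — so the importance ranking is
identical to the ascending p-value ranking by construction. Moran's I of
the response residuals (inverse-distance weights) is reported alongside
the fit as a spatial-autocorrelation diagnostic, not used as a gate.

## What the synthetic scenes emulate

The generator is first-class, tested code, and its defaults *are* the
study conditions exercised everywhere: a 50×50-pixel scene on a 300 m
grid, years 2017–2020 at three composites per month (36 per year, 144 in
total), NDVI baseline 0.55 with seasonal amplitude 0.25 peaking at
day-of-year 196 (mid-July, typical for temperate conifers; composites on
days 5/15/25 since the real product's timestamps are a cadence, not
dates), Gaussian composite noise (sd 0.02), elevation spanning 75–950 m,
and the drought in 2018.

Damage affects 30 % of forest pixels, sampled with probability increasing
with aridity (coupling 0.7), and multiplies a pixel's NDVI baseline and
amplitude by $1 - s$ from the drought year onward. Two realism parameters
matter for the statistics downstream:

* **Severity heterogeneity** (`damage_severity_spread`, default 0.75):
  each damaged pixel draws $s$ from
  $0.4 \times U(0.25, 1.75)$. Real die-off patches range from thinning
  crowns to complete loss; a single uniform step would make the two
  classes linearly separable and the logistic fit degenerate.
* **Label error** (`mask_error_rate`, default 0.02): a small, equal
  number of false-positive and false-negative damage labels, as any
  change-detection damage product carries.

Recovery is off by default (a persistent step change); a
`recovery_rate` parameter rebounds the suppression per post-drought year
to emulate partial recovery. Climate grids are generated at a 3× coarser
grid (900 m vs 300 m) to exercise the multi-resolution alignment the
mixed-source inputs require: precipitation increases and temperature
decreases with elevation (+35 % per elevation SD and a 6.5 K/km lapse at
the default coupling of 1), each variable carrying its own smooth spatial
noise field and a dry/warm/sunny growing season in the drought year. The
aridity gradient is therefore anti-correlated with altitude by
construction, which is what the zonation and altitude-regression checks
rely on.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: radiative-transfer or atmospheric
effects, clouds and realistic gap structure (only uniform random dropout),
bark-beetle spread dynamics (damage is spatially independent given
aridity, not contagious), interannual climate variability beyond the
single drought year, and mixed land cover within pixels.

## Problem sizes and runtime choices

Test and acceptance runs use the 50×50 default scene (2 500 pixels ×
144 composites), oracle comparisons use twenty 10×10×36 stacks, and the
parameter-recovery study uses 100 simulated data sets of n = 2 000 with
seven predictors — sizes at which every stage is exact or
well-conditioned and the whole suite completes in well under a minute of
compute. The spatial structures are smooth low-frequency cosine mixtures,
so nothing about the statistics depends on scene size beyond sampling
noise.

## Raster format

No compiled geospatial stack is part of the package's dependency set;
rasters are stored as ESRI ASCII grids — a georeferenced, plain-text,
GIS-interoperable format — with full double precision (round trips are
bit-exact) and a JSON sidecar carrying the CRS and band dates that the
`.asc` header cannot. All layers must share one CRS after alignment;
mixed-CRS stacks are rejected rather than silently reprojected per layer.
Extents are half-open, coordinates are cell centers, and the analysis
grid is the NDVI grid: the habitat indices carry the headline signal, so
every other layer is resampled to them (continuous fields bilinearly or
by mean aggregation, categorical by nearest neighbour, fine binary masks
by positive-fraction then a 0.5 threshold).

## Known limitations

* The equal-interval zonation is sensitive to the range of accumulated
  dMI; a single extreme pixel stretches the intervals. The breaks are
  stored with the map so any classification can be audited.
* Tukey–Kramer intervals assume homoscedastic groups; Bartlett's test is
  reported, but no Welch fallback is applied automatically.
* Trend classes rest on four annual values; the percentile threshold
  makes the *relative* trend statement robust, but individual slopes are
  noisy by nature.
* The greedy thinning maximises retained samples only heuristically; it
  guarantees the distance constraint, not optimality.
* Variable importance as |z| understates predictors whose effect is
  nonlinear or interactive; the model is deliberately a plain binomial
  GLM.
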