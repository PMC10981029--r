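# droughtDHI

Drought assessment of coniferous forests from dense NDVI time series,
built around the three **Dynamic Habitat Index (DHI)** components. The
package targets landscape ecologists and remote-sensing analysts who want
to quantify how a severe drought year reshapes forest productivity, track
multi-year recovery, and rank the environmental drivers of forest die-off
— and to validate every step of that workflow on synthetic scenes with
known ground truth.

## The method

For a pixel's within-year productivity series *p₁ … pₙ* (here NDVI, 36
ten-day composites per year), the three DHI components are

- **DHI_Cum** = Σ pₜ — annual cumulative productivity,
- **DHI_Min** = min(pₜ) — minimum vegetation cover,
- **DHI_Var** = σ(pₜ)/μ(pₜ) — seasonality (coefficient of variation).

Around this core the package implements the full analysis chain:

1. **Aridity zonation.** The monthly de Martonne index `dMI = P/(T + 10)`
   (P precipitation in mm, T air temperature in °C; lower = drier) is
   accumulated over the study period and split into four equal-interval
   zones (arid, semi-arid, semi-humid, humid).
2. **Trend analysis.** Per-pixel Theil–Sen slopes (median of pairwise
   slopes — robust to outliers and gaps) or moving-window OLS over the
   annual DHI values, classified with a 20 % percentile threshold into
   negative / indifferent / positive trends, and summarised as
   positive-to-negative area ratios per aridity zone and health stratum.
3. **Group statistics.** One-way ANOVA with Shapiro–Wilk / Bartlett / Q-Q
   assumption checks and Tukey–Kramer simultaneous contrasts comparing
   damaged vs non-damaged stands within years and between years.
4. **Health model.** A binomial logistic regression of damage status on
   16 candidate predictors (3 DHI components, 12 climate aggregates, and
   elevation), after spatial thinning, |r| > 0.8 correlation filtering and
   VIF > 5 collinearity filtering; reported with McFadden's pseudo R²
   (`1 − LL_fit/LL_null`) and |z|-based variable importance.
5. **Synthetic scenes.** A first-class generator produces multi-year NDVI
   stacks (seasonal sinusoids with a drought-year suppression of damaged
   stands), altitude-coupled climate grids at a coarser resolution, a DEM,
   and an aridity-coupled damage mask — so every stage above can be tested
   against known truth.

Rasters are read and written as georeferenced plain-text ASCII grids
(`.asc`, QGIS/GDAL-compatible) with JSON sidecars; multi-resolution layers
are aligned onto the 300 m analysis grid by bilinear, nearest-neighbour,
mean-aggregation or fraction resampling.

## Worked example

```r
library(droughtDHI)

cfg <- run_config(out_dir = "run1", scene = scene_params(seed = 1), seed = 1)
res <- run_pipeline(cfg)

res$zones
#> aridity_zones: breaks 309.99, 557.68, 805.37
#>       arid  semi-arid semi-humid      humid
#>       1695        628        139         38

res$model
#> Binomial logistic health model: n = 527, 7 predictor(s)
#>          term   estimate std_error       z         p
#> 1 (Intercept)   94.44820  66.33191  1.4239 1.545e-01
#> 2     dhi_cum   -1.79704   0.21425 -8.3874 4.971e-17
#> 3     dhi_var  -26.44141  75.21655 -0.3515 7.252e-01
#> ...
#> McFadden R2 = 0.8710

subset(res$ratios, component == "dhi_cum" & stratum == "total")
#>   component stratum       zone positive_px negative_px ratio empty
#> 1   dhi_cum   total       arid         300         399 0.752 FALSE
#> 2   dhi_cum   total  semi-arid         143          79 1.810 FALSE
#> 3   dhi_cum   total semi-humid          43          19 2.263 FALSE
#> 4   dhi_cum   total      humid          14           3 4.667 FALSE
```

Reading the output: the four-year 50×50 scene contains the 2018 drought
with 30 % of stands damaged. Annual productivity (`dhi_cum`) dominates the
health model (largest |z|), with lower productivity sharply raising the
damage probability; the model separates damaged from healthy stands very
well (McFadden R² 0.87, far above the 0.40 "very good fit" convention).
Positive productivity trends become more frequent relative to negative
ones toward the humid end of the aridity gradient (ratio 0.75 → 4.67),
and the altitude regression (`res$altitude_regression`) confirms that
accumulated drought eases with elevation (R² ≈ 0.83).

Each pipeline run also writes per-year and long-term component rasters,
the false-colour DHI composite, trend and zone maps, ANOVA/Tukey tables
and a JSON manifest into `out_dir`.

A command-line wrapper ships in `inst/cli/forestdhi.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","forestdhi.R",package="droughtDHI"))')" \
  --out-dir run1 --rows 50 --cols 50 --seed 1
```

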