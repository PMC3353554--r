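# phenokrige

Geostatistical analysis of plant flowering phenology from sparse
monitoring networks, in R.

Flowering phenology is usually studied as a time series at fixed sites.
`phenokrige` treats it as a *spatial* variable: given weekly phenophase
scores at a handful of georeferenced sampling points (a ten-site network
across a city and its adjacent sierra, in the motivating study of the
grass *Vulpia geniculata*), it interpolates the flowering state over the
whole study area, validates the interpolation, and links the resulting
maps to the airborne pollen curve recorded by a volumetric trap. The
audience is aerobiologists and spatial ecologists who want phenological
maps — and an idea of which areas feed the pollen curve — from a limited
number of sampled locations.

## The method

Flowering is scored on a five-phase scale from the fraction of open
flowers: 0 (before flowering), 1 (≤ 25 % open), 2 (full flowering,
25–75 % open), 3 (> 75 % open, anthers emptying), 4 (past flowering).
Each site's weekly value is the mean of five 1 m² quadrat scores, so the
working variable is a real number on [0, 4]. Per observation date the
pipeline runs:

1. **Screening.** Mean m, sample variance, extremes and coefficient of
   variation; outlier thresholds m ± 3s. Values strictly outside the
   thresholds are flagged.
2. **Structural analysis.** The empirical semivariogram by the method of
   moments, γ̂(h) = Σ(z_i − z_j)² / 2N(h) over distance-binned point
   pairs, fitted with an isotropic Gaussian model
   γ(h) = C₀ + C(1 − exp(−(h/A₀)²)) by bounded least squares
   (nugget C₀, structural sill C, range parameter A₀; effective range
   √3·A₀), scored by r² and RSS.
3. **Simple kriging.** With a known stationary mean m, the predictor
   Z\*(v) = Σλᵢ Z(xᵢ) + m(1 − Σλᵢ), the weights λ solving the covariance
   system C λ = c with Cov(h) = sill − γ(h); kriging variance
   sill − λᵀc.
4. **Validation.** Leave-one-out cross-validation: each site is removed
   and re-predicted from the rest; the OLS regression of actual on
   estimated gives the "regression coefficient" (slope near 1 = good
   interpolation) plus r², RMSE and bias.
5. **Mapping.** Kriged phase rasters (ESRI ASCII), integer phase-class
   maps, and the full-flowering mask: cells with a phase between 1.5 and
   2.5 mark populations shedding pollen at their maximum.
6. **Pollen.** Daily trap counts (grains/m³) summed into weekly pollen
   indices; the peak week and a per-date join of full-flowering map area
   with the pollen curve.

Because the original per-site field records are not published, the
package includes a first-class synthetic generator
(`simulation_config()`, `generate_network()`, `simulate_phenology()`,
`simulate_pollen()`): a Gaussian random field with Gaussian covariance
on top of a deterministic trend (weekly advance + altitude-driven
delay), observed as clamped means of five noisy quadrat scores. Every
stage of the pipeline is tested against it.

## Worked example

Ten real site coordinates ship with the package; one seed of the
synthetic generator supplies observations for six weekly visits.

```r
library(phenokrige)

pts <- cordoba_points()                       # 10 sites, 92-585 m a.s.l.
cfg <- simulation_config(seed = 11)
dss <- simulate_phenology(pts, cfg)
ds  <- dss[["2004-04-23"]]

descriptive_stats(ds)
#> <descriptive_stats> n = 10, mean = 0.940, variance = 0.130, range [0.53, 1.66]
#>   outlier thresholds (m +/- 3s): [-0.141, 2.022]

mod <- fit_variogram(empirical_semivariogram(ds, n_lags = 6))
mod
#> <variogram_model> gaussian: nugget C0 = 0.01641, partial sill C = 0.4156, range A0 = 1.126e+04 m
#>   sill = 0.432, effective range = 1.95e+04 m
#>   fit: r2 = 0.9305, RSS = 0.00734

loo_cross_validation(ds, mod)
#> <cv_result> n = 10 folds
#>   actual ~ estimated: slope 0.421, intercept 0.583, r2 0.052
#>   rmse 0.3611, bias 0.0897 (phase units)

g <- krige_grid(ds, mod, cellsize = 200)
classify_full_flowering(g)
#> <flowering_mask> band [1.50, 2.50]: area fraction 0.086

elevation_gradient_summary(g, pts)$statistic
#> [1] -0.9393939
```

Reading: no screening outliers (all values inside m ± 3s); the Gaussian
variogram fits the binned semivariances closely (r² 0.93, low RSS) with
an effective range beyond the network extent; the cross-validation
slope of 0.42 says that with n = 10 the interpolation is real but heavily
smoothed — the same order as the weaker published coefficients; early in
the season only ~9 % of the area is at full flowering; and the strong
negative altitude correlation (−0.94) shows the low-lying south
flowering ahead of the sierra, the spatial pattern the maps exist to
display.

The whole workflow, including weekly pollen aggregation and the
flowering/pollen join, runs end to end with

```r
run_pipeline(pipeline_config(out_dir = "out",
                             simulate = simulation_config(seed = 11)))
```

which writes the per-date tables (`stats.csv`, `variograms.csv`,
`cv.csv`, `area_fractions.csv`), the rasters under `rasters/`, the
pollen tables, a log, and a `manifest.json` of MD5 checksums that is
byte-identical across reruns with the same seed. A thin command-line
wrapper lives at `inst/cli/phenokrige.R`.

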