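---
title: "Geostatistical phenology with phenokrige: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geostatistical phenology with phenokrige}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenokrige)
```

## The problem and the working variable

A flowering season is monitored weekly at a small network of
georeferenced sites — in the motivating design, ten points spread over
roughly 17 × 10 km between a Mediterranean city and its sierra, five in
the warmer termomediterranean belt (92–217 m) and five in the
mesomediterranean belt (251–585 m). At each visit the flowering state
is scored on a five-phase scale driven by the fraction of open flowers
(open = stamens exerted): phase 0 before the first bloom, 1 up to 25 %
open, 2 (full flowering) up to 75 %, 3 while the anthers empty, 4 past
flowering. Ties at the 25 %/75 % cut-offs go to the lower phase — the
field definition is approximate, and a deterministic tie-break keeps
scoring reproducible. The recorded value per site and date is the mean
of five 1 m² quadrat scores, so the analysis variable is a real number
on [0, 4]. (Printed per-site extrema such as 1.75 are not multiples of
0.2, so quadrat scores cannot all be integers; the data model therefore
accepts any real in range.)

Coordinates are treated as planar metres with Euclidean distances
throughout. Over a ~17 km extent the distortion of a projected UTM-like
grid is negligible, and no geodesy is attempted.

## Stationarity, the variogram, and its fitting

Each date's field `z(x)` is modelled as second-order stationary with a
known mean — the assumption under which simple kriging is optimal. The
spatial structure is summarised by the semivariogram
`γ(h) = E[(z(x) − z(x+h))²]/2`, estimated by the method of moments on
distance-binned point pairs. Defaults: 6 uniform bins on `(0, max
pairwise distance]`. With ten sites there are at most 45 pairs, so more
bins would leave classes nearly empty; both the bin count and the
cut-off are arguments. The reported lag of a bin is the mean pair
distance inside it, and empty bins are dropped.

Phenology is a very continuous phenomenon in space, which motivates the
Gaussian model `γ(h) = C₀ + C(1 − exp(−(h/A₀)²))` — parabolic at the
origin, sill `C₀ + C`, effective range `√3 A₀`. Spherical and
exponential alternatives are available behind the same interface. The
fit minimises the (optionally pair-count-weighted) residual sum of
squares by bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) from a
deterministic multi-start: `C₀ = 0`, `C` at the data variance, `A₀` at
¼, ½ and 1 × the maximum lag. Unweighted RSS is the default because a
single unweighted RSS is the fit statistic practitioners of this
workflow report; `weighting = "pairs"` is one argument away.

Three numerical guards matter:

* `A₀` is bounded to `[10⁻⁹, 10] × max lag`. Below the smallest lag a
  Gaussian is indistinguishable from a flat line on the bins; far above
  it, `C` and `A₀` race to infinity along a ridge while the curve on
  the observed lags barely changes. The bounds keep parameters
  interpretable without affecting well-posed fits.
* A pure-nugget candidate (`C = 0`, `C₀` at the weighted mean
  semivariance) is always evaluated and wins ties. Consequently the
  fitted RSS never exceeds the pure-nugget RSS, and
  `r² = 1 − RSS/TSS` is guaranteed to land in [0, 1]. Exactly flat bins
  return the pure-nugget model flagged `degenerate_flat` with `r²`
  undefined.
* `r²` uses the TSS about the (weighted) mean empirical semivariance,
  mirroring how variography software reports goodness of fit.

## Simple kriging and its conventions

Predictions use `Z*(v) = Σλᵢ Z(xᵢ) + m(1 − Σλᵢ)` with weights from
`C λ = c`, covariances `Cov(h) = sill − γ(h)`. All data enter every
prediction (no search neighbourhood): with n ≤ 10 a neighbourhood would
only discard information. The system is solved densely
(LAPACK `solve`); grid prediction factorises the data covariance once
and solves for all cell centres simultaneously, which is why a grid
cell and a point call agree to 10⁻¹² or better.

Two conventions were genuinely open:

* **The stationary mean.** The published description of `m` in the
  estimator is garbled (a median-like formula spliced into the kriging
  equation). `phenokrige` takes `m` as the stationary mean, defaulting
  to the dataset's arithmetic mean, with `mean = "median"` and an
  explicit numeric override available. No further guessing is done.
* **The nugget at zero distance.** `Cov(0) = C₀ + C` on both sides of
  the system, so prediction at a sampled location returns the sample
  exactly (the datum is treated as error-free). The alternative —
  nugget as measurement error, giving smoothing at the data — is the
  `nugget_as_error` option, default off.

Kriging variance is `sill − λᵀc`, clipped to zero when round-off drives
it below −10⁻¹⁰ (with a warning beyond that tolerance). Estimates are
clamped to [0, 4] only at the map stage, and each clamped cell is
flagged, so the numerical prediction is never silently altered.

## Cross-validation

Leave-one-out: every site is deleted in turn and re-predicted from the
other n − 1, the variogram held fixed at the full-data fit (refitting
per fold is available but unstable at n ≈ 7) while the fold mean is
recomputed from the retained values so the held-out datum never leaks
in. The score is the OLS regression of actual on estimated — the
geostatistical convention for the cross-validation scatter; slopes
above 1 are possible and occur in the published coefficient tables,
consistent with reading the "regression coefficient" as a slope.
A useful degenerate case to know: under a pure-nugget model each
estimate is the mean of the other n − 1 values, which makes the
regression slope exactly −(n − 1); the package reports it honestly
(flagging only zero-variance estimates), and such rows should be read
together with the model's `pure_nugget` flag.

On matched synthetic fields (the model that generated the data also
krigs it; 100 points, 20 replicates) the median slope sits within a few
percent of 1 and the median bias within a few thousandths of a phase —
the calibration the acceptance script recomputes.

## Maps, the full-flowering band, pollen

Rasters default to the point bounding box padded 5 % with 100 m cells
(~170 × 100 cells here — instant at this scale). The full-flowering
band is inclusive, 1.5 ≤ phase ≤ 2.5, the rule linking maps to pollen
shedding; class maps round half up (1.5 → class 2) since no published
legend fixes the binning. Daily pollen counts aggregate into fixed
7-day windows anchored at the Monday on or before the first observation
(the week convention is otherwise unstated); incomplete windows are
flagged rather than dropped, ties for the peak week resolve to the
earliest and say so.

## What the synthetic generator does and does not emulate

`simulate_phenology()` draws, per date,
`z_t(x) = β₀ + r·t + β_alt·alt(x) + G(x)` with `G` a zero-mean Gaussian
random field realised exactly through the Cholesky factor of its
covariance over the point set (Gaussian covariance `C exp(−(h/A₀)²)`
plus an independent nugget; a 10⁻¹⁰ jitter guards the factorisation).
Exact factorisation was chosen over spectral approximations because
desk-scale networks (≤ a few thousand points) make an `n³` factor
irrelevant and exactness lets tests compare realised against configured
covariance directly. Observations are means of `n_quadrats` draws
`N(z, quadrat_sd²)`, clamped to [0, 4] after averaging (matching how
field means are recorded), with clamp flags.

Defaults are the study conditions, chosen once from the published
summaries and not revisited: 10 points on the real network's bounding
box, altitudes 92–585 m, six weekly dates; `β₀ = 1.8` phase at altitude
zero, `r = 0.5` phase/week (the published per-date means advance by
~0.5–0.6 per week), `β_alt = −0.003` phase/m (≈ 1.5 phases across the
~490 m altitude span, the order of the printed per-date min–max
spreads); GRF nugget 0.02, partial sill 0.15 phase², range 2000 m
(per-date variances of 0.14–0.48 in the published tables, most of it
trend); quadrat SD 0.5 (SE of a 5-quadrat mean ≈ 0.22). Dates are
conditionally independent given the trend — the true between-date
correlation is unknowable from published summaries, and this is a
deliberate simplification. Pollen emulation makes daily counts
proportional to the latent field's full-flowering fraction,
interpolated between visits, under median-preserving lognormal noise.

What passing tests therefore show: the pipeline's estimators recover
the structure this generator builds in — binned semivariances, sills,
kriging exactness, CV calibration, altitude-gradient sign. What they
cannot show: robustness to real-data features the generator omits —
temporal persistence of the random field across weeks, non-Gaussian
quadrat errors, preferential sampling, anisotropy along the valley, or
scoring drift between observers.

Reproducibility is by single integer seed; per-date sub-streams are
derived deterministically from it (all below 2³¹), so any one date can
be regenerated without simulating the others.

## Problem sizes in the test-suite

The suite exercises exhaustive-oracle comparisons at n ≤ 12 (hundreds
of random configurations), kriging oracles on 50 random datasets,
sill recovery on 500-point fields and CV calibration on 100-point
fields (20 replicates each, medians), and a 200-point unbiasedness
check — sizes at which every check runs in seconds while keeping the
Monte-Carlo statistics stable.

## Known limitations

* Simple kriging on a trended field: the altitude gradient violates
  stationarity, which inflates empirical semivariances at long lags and
  can push fits toward the `A₀` bound or to pure nugget. The workflow
  (shared with the original analysis) accepts this; universal kriging
  or trend removal is out of scope.
* With n = 7–10 sites the variogram is estimated from ≤ 45 pairs:
  per-date fits are volatile, which is visible in the published
  cross-validation coefficients (0.38–1.14) and equally in synthetic
  runs.
* One CRS is assumed; no reprojection, shapefiles or cartographic
  styling — rasters leave as ESRI ASCII grids.
* The screening step's sample variance uses the n − 1 denominator; the
  published tables cannot discriminate n vs n − 1, and n − 1 is the
  standard estimator at these sample sizes.
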