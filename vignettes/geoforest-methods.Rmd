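---
title: "Spatial prediction with buffer-distance forests: models, defaults and design choices"
author: "GeoForest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial prediction with buffer-distance forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GeoForest)
```

## 1. The two prediction routes

GeoForest interpolates point-sampled environmental variables to a grid
by two routes that share one data model and one evaluation battery.

**Model-based route (kriging).** The target is decomposed into a
deterministic trend and a stationary residual, `Y(s) = mu(s) + e(s)`.
With a constant mean, the best linear unbiased predictor at `s0` is the
ordinary-kriging weighted average `yhat(s0) = w' y`, with weights
obtained from the augmented linear system

```
[ C  1 ] [ w   ]   [ C0 ]
[ 1' 0 ] [ phi ] = [ 1  ]
```

where `C[i,j] = psill * rho(|s_i - s_j| / phi_r)` plus the nugget on
the diagonal, and the prediction-error variance is
`C(s0, s0) - w'C0 - phi`. The covariance model comes from a variogram:
we estimate the method-of-moments (Matheron) sample variogram
`gamma_hat(h) = sum (y_i - y_j)^2 / (2 N(h))` over distance bins and
fit nugget/partial-sill/range by weighted least squares (Section 4).
Skewed targets can be Box-Cox transformed first
(`(y^eta - 1)/eta`, natural log at `eta = 0`); for the log transform
the prediction and variance are back-transformed with the exact
lognormal moments `exp(yT + varT/2)` and
`exp(2 yT + varT) (exp(varT) - 1)`. Regression kriging composes a
linear trend in covariates with ordinary kriging of the trend
residuals.

**Learning route (buffer-distance forests).** A random forest is
trained on geographic covariates: one raster layer per training point
holding the Euclidean distance from every cell center to that point
(`bufferDistances`), or one layer per class (`classBufferDistances`),
optionally together with thematic layers, coordinates, and the
temporal covariates `cdate` (days since 1970-01-01) and `doy`
(day-of-year) for spatiotemporal data. Distances are exact
center-to-point values computed analytically, not raster-growth
approximations, so they are reproducible and oracle-testable. Because
the distance layers encode the full configuration of the sample, the
forest can express the same proximity information a variogram encodes,
without distributional or stationarity assumptions — at the price of
needing the n distance layers (a cap, default 1000 layers, guards
against unreasonably wide designs; per-class distances are the
suggested remedy).

Training rows are obtained by overlaying the points on the rasterized
layers (nearest-cell semantics, never interpolated), so a point's
self-distance is the small distance to its own cell center rather than
exactly zero — matching what the prediction grid will see.

## 2. Forest uncertainty: quantile regression forests

The fitted forest induces, at any location, observation weights
`alpha_i(s0)`: per tree, each in-leaf training observation receives its
bootstrap multiplicity normalized by the leaf total, and weights are
averaged over trees. They are nonnegative and sum to one, and the
weighted average `sum_i alpha_i y_i` reproduces the ensemble mean
exactly. Replacing `y_i` by the indicator `1{y_i <= t}` turns the same
weights into a conditional CDF, inverted with a deterministic
lower-step rule: the q-quantile is the smallest observed `y` whose
cumulative weight reaches `q` (no interpolation between observed
values). The prediction-error SD is estimated as half the central
68.27% interval, `sigma = (q_0.841 - q_0.159)/2`, which assumes a
symmetric conditional error; `sigmaFromDistribution()` offers the exact
second moment of the weighted distribution as an alternative when that
assumption is doubtful.

For categorical targets the same machinery runs as a probability
forest; for a binary target the class probability is mathematically
equivalent to a regression forest on the 0/1 indicator, a property the
test suite checks numerically.

**Multivariate (stacked) models.** Several variables observed on the
same support can be fitted as a single forest by stacking their rows
into one design and adding 0/1 type indicators (and, when relevant,
sampling-method indicators). Predicting one variable sets exactly its
indicator to 1. This shares the geographic covariates across variables
and lets cross-correlated variables borrow strength.

## 3. Tuning parameters and defaults

| parameter | default | meaning / why |
|---|---|---|
| `numTrees` | 500 | ensemble size; needs only to be "large enough", not tuned |
| `mtry` | `floor(p/3)` regression, `floor(sqrt(p))` probability | candidate covariates per split |
| `minNodeSize` | 5 regression, 10 probability | terminal node size for point prediction |
| `sampleFraction`, `replace` | 1, TRUE | classical bootstrap |
| `caseWeights` | none | bootstrap selection probabilities; use `1/measSd^2` for heteroscedastic surveys — weight-zero rows never enter any tree |
| `seed` | unset | fits are bit-reproducible given a seed and one thread |

Two documented departures from the point-prediction defaults matter in
practice:

* **Keep `mtry` high when a few covariates dominate.** In
  spatiotemporal designs where `cdate`/`doy` carry most of the signal,
  and in stacked multivariate designs where the type indicator must be
  available to split on, `mtry` should exceed `p/2` (the multivariate
  tests use `mtry = p`). This is a recommendation, never a silent
  override.
* **Use larger leaves for interval estimation.** QRF quantiles are
  consistent only with terminal nodes that grow with n; fully grown
  trees concentrate the weights on a few neighbours and understate the
  conditional spread. For interval-focused fits we use
  `minNodeSize ~ 0.1 n` (40 at n = 300 in the calibration study below),
  which restores near-nominal coverage at under 2% RMSE cost. Point
  predictions keep the small-leaf default.

## 4. Numerical choices

* **Variogram fitting** minimizes
  `sum N(h)/gamma_model(h)^2 (gamma_hat - gamma_model)^2` over
  (nugget, psill, range) with L-BFGS-B from five deterministic
  data-driven starts; ties resolve to the lowest objective. The range
  is bounded above by 3x the maximum observed lag — beyond the lags it
  is not identifiable and unbounded fits produce arbitrary huge ranges.
  Failure of every start falls back to a pure-nugget model with a
  warning. Default `maxDist` is half the maximum pairwise distance;
  empty bins are dropped; a degenerate all-equal-distance configuration
  returns a single bin with a warning.
* **Kriging solves** use one dense factorization of the augmented
  system per (training set, neighborhood); variances within `-1e-6` of
  zero are clamped to zero, more negative values warn. Duplicate
  coordinates with a zero nugget raise an error naming the offending
  points (they make the system exactly singular); with a positive
  nugget they are legitimate replicate measurements. The default
  neighborhood is global; `nmax` enables nearest-m local solves, which
  also screen out far-away observations entirely.
* **Regression-kriging variance** adds the trend variance
  `MSE (1 + x0'(X'X)^-1 x0)` and the residual kriging variance without
  their cross-term; the full integrated (universal-kriging) variance
  would require jointly estimating trend and covariance, which this
  package deliberately leaves to the model-based route's reference
  software. The reported variance is therefore approximate (slightly
  conservative).
* **Grid geometry** is row-major, north-up, square cells; cell
  membership uses half-open intervals so every in-extent point maps to
  exactly one cell. Points on masked cells yield missing covariates
  (with a count), not errors.
* **GRF simulation** factors the dense covariance of the cell centers
  (Cholesky) after adding a `1e-10 * sill` diagonal jitter, then adds
  iid nugget noise; grids are capped at ~6000 cells, which is exact and
  fast at desk scale. Larger surfaces should be simulated in tiles or
  with spectral methods out of scope here.
* **Second-stage sampling** greedily accepts cells in decreasing
  predicted-error order (ties broken row-major) subject to a minimum
  pairwise spacing, returning the maximal feasible set with a warning
  when the request is infeasible.
* **Grid files** are ESRI ASCII rasters (one per layer, full double
  precision, `NA` as the no-data token) indexed by a JSON manifest
  carrying layer names, roles, CRS tag and geometry: a plain-text
  format that round-trips exactly and diffs cleanly under version
  control. Points travel as CSV with a configurable column mapping.
  Coordinates are always treated as planar; lon/lat input triggers a
  warning that distances are computed in coordinate units.

## 5. Evaluation battery

Cross-validation refits *everything* per fold — the variogram for the
kriging routes and, for the forest route, the buffer-distance layers
themselves, rebuilt from the training-fold points only. This makes
forest CV k times more expensive but prevents the held-out locations
from leaking into the geographic covariates (the report records the
per-fold covariate counts so the guard is checkable).

Metrics follow the standard conventions: RMSE; mean error as
*predicted minus observed*; `R2 = 1 - SSE/SST` with SST about the
observed mean of the validation points; Pearson correlation; and Lin's
concordance correlation, which penalizes bias as well as imprecision
and never exceeds `|rho|`. Uncertainty calibration uses z-scores
`(yhat - y)/sigma` (variance well below 1 = uncertainty overestimated,
well above 1 = underestimated; points with `sigma = 0` are excluded and
counted) and accuracy plots: empirical coverage of central intervals
symmetric in probability around the median versus their nominal level.

**Residual structure fraction.** The CV-residual variogram is fitted
like any other; we summarize it by the share of residual variance the
fitted model accumulates between the median nearest-neighbour distance
and the maximum observed lag. This span-based definition matters in
both directions: a fitted range far below the point spacing is
observationally pure nugget, and a fitted "structure" whose correlation
is ~1 at every observed lag is observationally a constant — neither is
autocorrelation the data can see. When the fitted range is resolvable
inside the lag span the statistic reduces to the classical
`psill/(nugget + psill)`. Fractions below 0.2 are reported as "no
residual spatial autocorrelation".

## 6. What the synthetic generators emulate — and what they do not

The generators reproduce the *statistical structure* of the archetypal
use cases entirely from code: stationary Gaussian random fields with
known variograms (and a lognormal option for skewed, strictly positive
concentration data); uniform or parent-offspring clustered sampling at
cell centers; two-source heteroscedastic surveys (`makeDataset` records
each point's true noise SD so inverse-variance case weights can be
tested against the noise-free truth); multinomial class maps as the
argmax of K latent fields; and zero-inflated seasonal daily station
data (seasonal cosine in `doy` + AR(1)-evolving spatial field + nugget,
left-censored at a threshold).

They deliberately do **not** emulate: non-Gaussian dependence
(copulas), anisotropy, non-Euclidean proximity (streams, roads, cost
surfaces), covariate-driven trends with real remote-sensing texture,
measurement drift, or preferential sampling aligned with the target.
Tests passing on these fields therefore demonstrate correctness of the
algorithms and calibration under the stated model, not performance on
any particular real survey; on real data the relative merits of the
two routes will also depend on how informative the thematic covariates
are.

## 7. Study conditions used by the verification battery

Problem sizes were chosen once, as desk-scale analogues of typical
surveys (a few hundred points on a few thousand cells):

* solver oracle: 50 random configurations of 3-10 points;
* variogram recovery: 20 fields, 40x40 grid, exponential
  (nugget 0.1, psill 1, range 5), n = 300 samples each;
* z-score calibration: 10 replicates of fivefold CV with the true
  variogram, 30x30 grid, n = 100;
* forest-vs-kriging agreement: 40x40 grid, range 8, n = 150, map
  correlation over all 1600 cells;
* interval calibration: n = 300 training points, 500 held-out cells,
  `minNodeSize = 40` (Section 3), nominal levels 0.5-0.9;
* residual de-correlation: 20 replicates, both routes, n = 100;
* case-weight study: two sources with SD ratio 3 (0.5 vs 1.5, the
  noisy source's error comparable to the field SD) mixed 20/80 — as in
  real soil surveys where the less accurate source is several times
  more numerous — n = 150, weighted by `1/measSd^2`, judged by RMSE
  against the noise-free truth on the remaining cells over 20
  replicates;
* multivariate stacking: two fields with correlation ~0.8 observed at
  the same 120 locations; the stacked model's per-type R2 against the
  truth is compared with separately fitted models.

`scripts/acceptance.R` recomputes all of these from scratch under a
single `--seed` in about a minute.

## 8. Known limitations

* Isotropic variograms only; no anisotropy, no REML/ML fitting, no
  Bayesian variogram uncertainty.
* Spatiotemporal support is covariate-based (`cdate`, `doy` + buffer
  distances); there is no space-time kriging counterpart.
* Forest predictions cannot extrapolate beyond the training-target
  range — a hard property of the estimator (every prediction is a
  convex combination of training values), restated as a test. Kriging
  can extrapolate; whether that is a feature depends on the
  application.
* QRF coverage is near-nominal but mildly sensitive to leaf size
  (Section 3); with small-leaf defaults the 90% intervals run a few
  points short on smooth fields.
* The RK variance omits the trend-residual cross-term (Section 4).
* No reprojection: all inputs must share one projected CRS.
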