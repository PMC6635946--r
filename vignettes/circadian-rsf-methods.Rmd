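---
title: "Methods: circadian resource selection with CRW availability nulls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circadian resource selection with CRW availability nulls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical method it
implements, the assumptions baked into each stage, the tunable
parameters and their defaults, and the design decisions taken where the
workflow was genuinely open. It states no empirical result beyond what
the test suite and `scripts/acceptance.R` themselves compute.

## 1. The use–availability design

The central object is a case–control table of *location records*: used
records (case 1) are an animal's quality-controlled GPS fixes;
available records (case 0) are points from five correlated random
walks (CRWs) simulated inside that animal's availability region and
carrying the same animal id. The model is a weighted binomial-logit
mixed regression of case status on landscape covariates with a
per-animal random intercept:

$$\mathrm{logit}\,P(y_{ij}=1) = \mathbf{x}_{ij}^\top\beta + u_j,\qquad
u_j \sim N(0, \sigma^2_u).$$

Two fixed-effect families are fitted:

* **Landscape use**: indicator terms for the habitat class of the
  containing raster cell, optionally crossed with the day/night factor.
  Waterbody is excluded as a predictor class (it is unsuitable habitat
  and also removed from availability), and sex is never included in
  this family. Reference levels: habitat = woodland/scrub (the dominant
  natural class), time = day.
* **Landscape distance**: z-standardised shortest distances to all
  seven feature classes, each entering with degree 1 or 2 (see the
  curvature screen below), in additive form or fully crossed with time
  and then sex (three-way interaction in the richest candidate).
  Reference sex = F.

Candidate structures (null, additive, ×time, ×time×sex) are compared on
identical records by
$\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$ with Akaike weights
$w_m \propto \exp(-\Delta_m/2)$, computed stably after subtracting the
minimum. $k$ counts all fixed coefficients plus one variance parameter
when the random intercept is present. Ties in AICc rank the model with
fewer parameters first, then input order. Fit is summarised by the
Nakagawa–Schielzeth decomposition with the logit distributional
variance $\pi^2/3$:
$R^2_m = \sigma^2_f/(\sigma^2_f+\sigma^2_u+\pi^2/3)$ and
$R^2_c = (\sigma^2_f+\sigma^2_u)/(\sigma^2_f+\sigma^2_u+\pi^2/3)$,
where $\sigma^2_f$ is the variance of the fixed linear predictor over
the fitted records.

**Estimation.** The random-intercept likelihood is maximised by the
Laplace approximation (delegated to `lme4::glmer`); the fixed-only
structure uses `stats::glm`. AICc, weights and $R^2$ always come from
this package's own formulas, with $\ell$, $\hat\beta$ and
$\hat\sigma^2_u$ extracted from the fit. A hand-rolled IRLS oracle in
the test suite confirms that fixed-only fits agree with an independent
implementation to $10^{-4}$.

**Random-structure choice.** The same fixed structure is fitted with
and without the intercept; the intercept is kept only when it improves
AICc by more than 2 units, a tie keeping the simpler structure. The
winner is used for the whole candidate set.

**Weights.** The default scheme is `none` (all weights 1): under the
1:5 used:available ratio the no-selection baseline probability is then
exactly $1/6 \approx 0.17$, which is the reference line drawn on
response curves and the calibration target recomputed by
`scripts/acceptance.R`. An `equalize` scheme
(available weight = n_used/n_available = 0.2) is provided for users who
want balanced pseudo-likelihood contributions, but it moves the
baseline to 0.5 and is therefore not the default.

## 2. Quality control

A fix is discarded iff HDOP > 8, satellites < 3, height > 100 m ASL,
speed > 8 m/s, or it falls within 8 h after a capture event of its
animal (plus optional per-animal trapping windows). Comparisons are
strict, so boundary values (HDOP exactly 8, 3 satellites, 100 m,
8 m/s) are retained. Each removed fix is logged with the first matching
rule in that order. Speed uses the collar's reported column where
present and is otherwise recomputed as displacement over elapsed time,
the first fix inheriting its following segment. Heights are interpreted
as metres above mean sea level. A displaced (spike) fix inflates the
recomputed speed of its successor as well, so the speed rule may remove
one neighbouring clean fix per spike; this collateral is bounded to ±1
fix, logged, and verified in the tests.

## 3. Availability regions and CRW nulls

The availability region of an animal is its 100% minimum convex
polygon (convex hull of all retained fixes, area by the shoelace
formula) dilated outward by $b = \tfrac12\sqrt{A}$, with waterbody and
nodata cells excluded. "Buffer" is read as dilation of the hull by
$b$ — the standard GIS buffer of the home-range polygon. Membership is
a point-level test (distance to hull ≤ b, containing cell not
water/nodata/outside), and the region's area is rasterised
(cell count × cell area).

Each CRW reproduces the source trajectory's fix count and exact
timestamps (gaps included), starts uniformly in the region (rejection
sampling in the bounding box), takes an initial heading uniform on
(−π, π], and then draws step lengths and turning angles independently,
with replacement, from the animal's own empirical multisets. Lengths
are the n−1 Euclidean displacements; turning angles are the n−2 signed
heading changes wrapped to (−π, π] with left turns positive. A
zero-length step has no heading: it inherits the previous one
(contributing angle 0), and angles adjacent to zero-length steps are
excluded from the multiset.

**Boundary handling.** A proposed point outside the region triggers
redraws of the (length, angle) pair, up to 100; if all fail, up to 100
angle-only redraws at the smallest observed step length (a minimal,
logged bias toward short steps at hard boundaries); if that also fails
the walk errors out as over-constrained rather than looping forever.
Redraws are evaluated in vectorised batches, which changes nothing
statistically (i.i.d. proposals) but keeps 25,000-step simulations in
seconds.

**Reproducibility.** All generators consume one root seed from which
per-animal and per-walk child seeds are derived by fixed splitting, so
results are independent of iteration order; every stage is a pure
function of (inputs, config, seed), which the pipeline tests verify
byte-for-byte.

## 4. Covariates

Distances are computed from cell centre to the nearest cell centre of
each class by an exact two-pass Euclidean distance transform
(Felzenszwalb–Huttenlocher lower-envelope method), verified against an
exhaustive brute-force scan on random rasters. Measuring to rasterised
features rather than vector geometry introduces at most
cell_size/√2 ≈ 14 m error at the default 20 m resolution. A class
absent from the raster is an error, not an infinite distance.

The Pearson screen reports all feature pairs with |r| > 0.7; it is
advisory (nothing is dropped automatically), and zero-variance features
are reported as undefined rather than silently skipped.

The curvature screen automates what is usually a visual inspection: a
binomial additive fit of case status on a fixed 3-df cubic spline of
each distance (weighted as the main model), evaluated on a 100-point
grid. The smooth is declared non-monotone — and the feature given a
quadratic term — only when both its total rise and total fall exceed
twice the mean pointwise standard error; this tolerance stops noise
wiggle around a flat or monotone trend from registering as curvature
(a flat smooth counts as monotone). Non-convergence falls back to
degree 1 with a warning. The packaged default recipe (quadratic for
woodland/scrub, farmland, coastal, wetland and road distances; linear
for housing and waterbody) can be overridden per feature, and the
screen can be run instead.

Standardisation is $(v - \bar v)/s$ with centre and scale taken over
the combined used+available pool and stored in a recipe, so
prediction-time grids and maps reuse the training transform exactly.
Quadratic terms are built on the standardised scale ($z$ and $z^2$);
the alternative (standardise $d$ and $d^2$ separately) differs only by
an affine reparameterisation of the linear predictor, so fitted
probabilities are unchanged — a stated choice where the convention was
ambiguous. Distance caps — min(first interior turning point of the
3-df smooth, 500 m) — bound presentation ranges (curve axes) only and
never alter the data a model is fitted to.

## 5. Solar classification

Solar position uses a low-precision NOAA/Meeus-class algorithm
(declination, equation of time, hour angle), accurate to a few
hundredths of a degree; dawn/dusk are the crossings of elevation
through −(depression angle), bracketed on a 10-minute grid and refined
by root finding to about one second. The depression default is 6°
(civil twilight), the conventional operational dawn/dusk; it is
configurable, as published analyses do not always report the angle
used. "Local date" is the UTC day shifted by lon/15 hours, avoiding
civil time-zone and DST tables; since the shifted window is centred
near local solar midnight, dawn and dusk fall inside one window at all
non-polar latitudes. Day is the half-open interval dawn ≤ t < dusk;
polar no-event days classify whole-day by polarity, and single-crossing
transition days fall back to the instantaneous elevation, so the
classifier is total. One representative site coordinate per dataset
suffices for study areas a few tens of km across (solar-time
differences are well under a minute); tests pin the classifier to an
independently coded NOAA-formula calculator within 5 minutes at ten
site/date combinations, including the nominal site latitude of −38.5°.

## 6. The synthetic-data module

The generator emulates the statistical structure the analysis assumes:
a patchy categorical landscape (smoothed-noise area classes,
one-cell-wide road polylines, contiguous waterbodies), a two-sex
population, and movement by candidate-based step selection — at each
15-min step, 20 candidate endpoints are drawn from a gamma step-length
distribution (shape 1.5, scale 30 m, plausible for a medium-sized
herbivore at this fix interval) and a wrapped-normal turn distribution
(mean resultant length 0.578 ≈ 60° circular sd), and one is chosen
with probability ∝ exp(β[class]) using the day or night coefficient
vector for the step's solar time; water and off-map candidates get
probability zero. GPS degradation adds Gaussian positional error and
plants disjoint ⌈fraction × n⌉-sized sets of HDOP, satellite, altitude
and speed-spike defects, each recorded in a truth table.

Because selection acts on candidate *steps* while the fitted model is
a point-wise RSF, recovered coefficients match the generator in sign
and rank, not magnitude — the recovery tests assert exactly that. The
generator moves every step (no rest bouts), plants defects
independently at random (real collar failures cluster), and uses
isotropic movement; passing tests therefore demonstrate correctness of
the pipeline's logic and calibration, not realism of any particular
field system. Default study conditions used throughout the tests: an
80 × 80-cell landscape at 20 m, 10 animals (sex ratio 22/48), 500
fixes each; the heavier recovery suites use 5–6 animals × 300–400
fixes × 20 replicates, sizes at which every property tested is stable
under reseeding.

## 7. Predictions

All reported predictions are population-level (random intercept at its
mean, zero), matching map-scale extrapolation that is agnostic to
individual identity. Selection indices are inverse-logit fixed-effect
predictions per habitat × time with delta-method 95% CIs computed on
the linear predictor and transformed endpoint-wise. Use-family maps
assign each cell its class × time prediction, masking water, nodata and
classes unseen in training; distance-family maps standardise each
cell's seven distances with the stored recipe and predict through the
polynomial expansion, with other-feature values at the pooled mean
(z = 0) for response curves — the mean, not observed values, is used
for time-invariant covariates, a stated choice. Maps are emitted at a
configurable resolution (default 20 m) by nearest-neighbour resampling
and written as ASCII grids and PNGs; curve/map consistency and a
brute-force per-cell prediction check are part of the test suite.

## 8. Known limitations

* Availability is a hard geometric region; no kernel home ranges or
  parametric (fitted) CRWs.
* Step lengths and turning angles are resampled independently;
  empirical (length, angle) pairs can be kept together via the joint
  resampling option, but that is not the default.
* No treatment of spatial or temporal autocorrelation within
  trajectories beyond the per-animal random intercept; no random
  slopes, conditional-logistic (step-selection) estimators, or
  Bayesian fitting.
* Raster-native distances; vector features and least-cost or
  anisotropic distances are out of scope.
* The QC rules are exactly the four thresholds plus exclusion windows;
  no additional biological-plausibility screening.
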