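---
title: "Modelling trail-mediated plant spread: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling trail-mediated plant spread: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(trailspread)
```

`trailspread` reconstructs and simulates how a point of introduction (a
station or settlement) and linear corridors (hiking trails) shape the
spread of a plant across an Arctic coastal landscape. The pipeline has
four analysis stages — establishment-kernel fitting, stochastic spread
simulation, density attribution, and a terrain-preference randomisation
test — plus a synthetic data generator that lets every stage be exercised
and validated without any field data. This vignette explains the models,
the defaults and the design decisions; the README shows a compact worked
example.

## The establishment kernel and its two source assumptions

The central object is the *establishment kernel* (also called the
effective dispersal kernel): the probability density of the distance
between a source individual and a newly established individual. It folds
dispersal and establishment success into a single observable distribution,
which is exactly what an abundance survey can constrain.

From a transect survey the package builds two establishment-distance
datasets:

* **local spread** (`distances_local()`): each individual's source is its
  nearest other individual. Records are abundance-expanded — a record of
  abundance *k* stands for *k* individuals within the 50-cm GPS recording
  radius — and nearest-neighbour distances are floored at 0.25 m (half the
  recording radius), because distances below the aggregation resolution are
  not observable and a hard zero would break the log-supported families.
* **trail spread** (`distances_from_trail()`): each off-trail individual's
  source is the nearest individual *on the trail*, formalising the
  hypothesis that the trail acts as a spreading corridor.

Six candidate location–scale families can be fitted to either dataset:
log-normal, Cauchy, exponential, exponential power, chi-square (real-valued
degrees of freedom) and Rayleigh, all parameterised `(shape?, location,
scale)` so that published parameter tables plug in directly. The
"exponential power" family deserves a warning label: several unrelated
densities carry this name. Here it is `b z^(b-1) exp(1 + z^b - e^(z^b))`
on `z >= 0`, the form used by the common scientific-computing fitters; its
mean and skewness have no closed form and are integrated numerically
(adaptive quadrature, tolerance 1e-8).

**Estimation vs. ranking.** Parameters are estimated by maximum likelihood
(Nelder–Mead on a reparameterisation that keeps the location strictly below
the sample minimum for families supported on `x > location`, and scale and
shape positive). Families are *ranked* by the sum of squared errors between
the fitted pdf and the density-normalised distance histogram (Sturges bins
on `[0, max]`), with BIC and family name as tie-breakers. We deliberately
separate the two: histogram SSE is a sensible model-selection statistic but
a poor estimator (it depends on binning and wastes information), while ML
is statistically efficient but would hand the ranking to families that can
chase point masses. A pure histogram-SSE estimation mode
(`fit_family(..., method = "sse")`) is kept behind a flag for fidelity
experiments with SSE-based fitting stacks.

Summaries follow the conventions of the field: `kernel_mean()` reports the
closed-form mean establishment distance where it exists and the median
(= location) for the mean-free Cauchy; `kernel_skewness()` exposes both the
analytic standardised third moment (undefined for Cauchy, which errors
rather than silently switching) and a seeded sampling estimator. High
positive skewness flags fat upper tails, i.e. rare long-distance
establishment events that matter for invasion acceleration.

## The stochastic spread simulator

The simulator is a yearly-updated occupancy model on a square grid
(default 5-m cells) over a simulation period (default 1928–2018, the span
from first record to last systematic survey).

1. **Suitability.** A cell can be colonised iff it is not water (sea or
   lake) and lies at or below an elevation threshold — by default 137 m,
   the highest elevation at which the species was observed
   (`elevation_threshold()` recomputes this from any occurrence set).
2. **Kernel discretisation.** The fitted 1-D distance pdf is stamped onto
   a `(2r+1) x (2r+1)` stencil: the weight at cell offset distance `z` is
   `pdf(z) * cell_size`, read as the per-year establishment probability
   contributed by one occupied source cell at that distance. The centre
   cell is evaluated at `z = cell_size/2` so families with a pole at the
   origin stay finite. The truncation radius `r` is the `truncation_q`
   distance quantile (default 0.99) in cells; heavy-tailed families whose
   quantile explodes (Cauchy) are capped at `max_radius` with a warning.
   If the stencil mass exceeds 1 it is rescaled to sum to 1. Two points
   here are genuine modelling choices rather than consequences of the
   fitting: (a) the 1-D density is applied along every bearing with no
   `1/(2*pi*z)` ring correction, matching the direct 2-D evaluation used
   in the source analyses — a ring-corrected mode is exposed
   (`ring_correction = TRUE`) for sensitivity analysis, and (b) nothing in
   the fitted pdf dictates how it normalises into a per-cell annual
   probability; `pdf * cell_size` is the stated convention of this
   implementation.
3. **Convolution.** The establishment probability surface is the
   convolution of the occupied state with the stencil, computed by
   zero-padded 2-D FFT (padded to highly composite sizes, kernel spectrum
   precomputed once per run). The test suite holds the FFT path to the
   nested-loop direct convolution at 1e-9.
4. **Scenarios.** Under `no_trail_effect` only the local kernel applies,
   from every occupied cell. Under `trail_effect` the trail kernel
   additionally applies from occupied cells on the trail, and the two
   probabilities combine as independent sources:
   `P_e = 1 - (1 - P_local)(1 - P_trail)`. The complement product keeps
   `P_e` in `[0, 1]` without ad-hoc capping; it is the natural reading of
   "the trail kernel applies additionally", though other combinations are
   conceivable.
5. **Stochastic establishment.** Every unoccupied suitable cell draws an
   independent threshold `T_e ~ U(0,1)` each year and establishes iff
   `P_e > T_e` — a Bernoulli(`P_e`) trial; the boundary case has measure
   zero, so strict vs. non-strict comparison is immaterial. Occupied cells
   never revert (no demography, seed banks, density dependence or Allee
   effects — deliberate non-goals).

Replicate `k` of a run is seeded `base_seed + k` with one RNG stream per
replicate, making every history bit-reproducible. The replicate-averaged
arrival map ignores replicates that never colonise a cell
(sentinel-aware averaging); a companion layer counts colonising
replicates, which is also what the evaluation uses ("majority occupied").

**Evaluation.** `sensitivity()` scores a simulation against presence-only
survey records as TP/(TP+FA): each observed presence, aggregated to an
evaluation block (default 1000 m, the systematic survey unit; use the cell
size for point records), is a true presence if any replicate-majority-
occupied cell falls in its block by the survey year. Block-level
aggregation is our choice, made because systematic records are grid-centre
points and a 5-m cell-level match would be meaninglessly strict for a
model that only claims to capture the *extent* of spread.

## Density attribution: KDE + GLM

`kde_density()` evaluates a 2-D Gaussian kernel density estimate of the
occurrence records at every cell centre, with Scott's rule on the full
sample covariance (`H = cov * n^(-1/3)`) as the default bandwidth and a
scalar isotropic override for degenerate scatters. The surface is min–max
normalised to `[0, 1]` rather than integral-normalised: the downstream GLM
wants a bounded response, and "normalised KDE" is the convention the
reference tables use.

`fit_density_glm()` regresses that response on z-scored predictors —
distance from the station, distance from the closest trail, elevation, and
the station x trail interaction — with `stats::glm()`. A negative station
and trail term with a positive interaction is the signature of spread that
started at the station and travelled along the trails. Two families are
supported because the source description is genuinely ambiguous (the text
says Gaussian errors, the result table says Poisson): for `gaussian` the
package reports the classical adjusted R² and labels it as such; for
`poisson` it reports the McFadden adjusted pseudo-R²
`1 - (logL_full - k)/logL_null`, evaluating the Poisson log-likelihood
directly with `lgamma` so a continuous response is handled. Neither family
is asserted to be "the" reference model. `partial_r2()` refits the model
without each term and reports `(SSE_reduced - SSE_full)/SSE_reduced`
(deviance analogue for Poisson) — the share of the reduced model's
unexplained variation that the term accounts for. No spatial
autocorrelation correction is applied; the reference analysis fits an
ordinary GLM and so do we, which means standard errors on autocorrelated
surfaces should be read as descriptive, not inferential.

## Terrain preference: the joint-shift randomisation test

On gravelly Arctic terrain, brightness is a usable substrate proxy: gravel
is brighter than vegetation or exposed soil. `relative_luminance()`
converts an RGB orthomosaic to Rec. 709 relative luminance
(`0.2126 R + 0.7152 G + 0.0722 B` on [0,1] channels).

`randomisation_test()` asks whether individuals sit on brighter pixels
than expected *while preserving the internal geometry of the point
pattern*: every iteration translates all points rigidly by one shift drawn
uniformly and independently per axis from `[-max_shift, +max_shift]`
(default 10 m). Rigid translation keeps all pairwise distances fixed, so
the clustering produced by local dispersal cannot masquerade as terrain
preference. Three decisions are worth stating:

* "Uniform in both directions" is read as a *signed* uniform per axis;
  unsigned shifts could never re-centre the pattern.
* Shifts that would push any point off the raster are rejected and
  redrawn, which preserves uniformity on the admissible set (clamping
  would pile mass on the boundary). With 1e4 consecutive failures the test
  errors instead of silently degrading.
* The p-value counts the observed iteration among the `n` (default 1000)
  iterations: `p = #(medY_i >= medY_0)/n` including `i = 0`, so
  `p >= 1/n` and the estimator is conservative.

The test statistic is the median sampled luminance (nearest-pixel lookup),
which also makes the p-value invariant under any monotone rescaling of
luminance — a property the tests verify by squaring the raster.

## The synthetic study system

`synth_config()` + `make_landscape()` generate a strandflat-like coastal
landscape: sea behind a wiggling coastline, elevation rising inland
(0–150 m) with raised beach ridges parallel to the coast and a smooth
random field, 2–5 lakes on low ground, a station on land near the coast,
and two trails starting at the station ("east" along the coast, "south"
inland across the ridges). All outputs are pure functions of the
configuration including its seed.

The generator's defaults are the study conditions the package is validated
under, chosen once:

* grid 400 x 400 cells at 5 m (2 x 2 km); the heavier simulation tests use
  200 x 200 (1 x 1 km), stated here as the package's own choice of problem
  size;
* true kernels equal to the best published fits — local three-parameter
  log-normal (0.8611, −0.0799, 1.3177; mean ≈ 1.83 m/yr) and trail
  log-normal (0.5760, −9.9562, 33.6560; mean ≈ 29.77 m/yr) — so
  closed-loop tests run under the fitted study conditions;
* simulation period 1928–2018, systematic surveys 1994/2014/2018,
  transect survey 2023;
* an on-trail individual share of 86.9%, the published survey proportion.

`simulate_truth()` runs the spread simulator itself (trail-effect
scenario) rather than an independent point process: the kernels are
*establishment* kernels, so simulating establishment directly is the
semantically matching generator and makes parameter-recovery tests
closed-loop. Surveys then observe that truth: `sample_systematic_survey()`
emulates the 1-km presence grids (one block-centre record per occupied
block); `sample_transect_survey()` walks the south trail placing T-shaped
transects every 50 m (2 x 50 m trail plot, perpendicular 2 x 100 m
off-trail plot, eastward only — the west side is a protected bird
reserve), scatters `1 + Poisson(lambda)` individuals in each occupied
sampled cell, aggregates them at the 50-cm recording resolution, and stops
after five consecutive empty trail plots. The trail-plot lambda is
calibrated so the *expected* on-trail share of individuals equals the
configured share; detection within plots is perfect, because the emulated
protocol treats plots as censuses. Early unsystematic records have no
documented effort model, so nothing stronger than "sparse records near the
station" is claimed for that class.

`render_luminance()` builds a 10-cm orthomosaic window around given
occurrences — dark vegetated background, bright gravel band along the
trail, brighter ridge crests — and re-places each occurrence within 3 m of
its position with probability proportional to
`exp(strength * luminance)`. Strength 0 gives no terrain association
(the null-calibration case); the RGB companion is constructed (grey
gravel, luminance-scaled green vegetation) so Rec. 709 luminance recovers
the luminance channel to machine precision.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: GPS error, imperfect detection, observer
variation between historical surveys, shadows or radiometric artefacts in
the orthomosaic, microhabitat suitability beyond water and elevation, and
any demographic process. The synthetic landscape is a statistical stand-in
with the right structure, not a reconstruction of any real geography.

## Numerical and I/O choices

* Coordinates are planar projected metres throughout; no geodesy. Grids
  are north-up with half-open cell extents; boundary points belong to the
  higher-index cell; cell membership is by cell centre. Row/column indices
  are 1-based in the R convention.
* ESRI ASCII grid is the canonical raster format (plain text, hand
  parseable); TIFF is supported with an ESRI world file carrying the
  georeferencing. Trails and the station travel as GeoJSON in metres;
  occurrence records as `x,y,year,abundance,plot_class` CSV.
* The default trail width for on-trail masks is 2 m (the physical trail
  and trail-plot width); the spread simulator rasterises the trail at
  twice the cell size instead, so that a 5-m grid has a connected trail
  corridor for the trail kernel to act from.
* Optimiser failures in `fit_family()` are errors naming the family and
  the last objective; in `rank_fits()` they are collected per family and
  reported, so one refusing family cannot sink the ranking.
* `Rscript inst/scripts/trailspread-cli.R <synth|kernels|density|spread|terrain>`
  is a thin command-line wrapper over these functions for shell pipelines.

## Known limitations

* The local-spread distance sample from a transect survey carries a point
  mass at the 0.25-m floor (co-located individuals); unbounded-density
  families can chase it under pure ML. The SSE ranking is robust to this,
  but single-family ML fits on such data should be inspected.
* Simulated "potential dispersal range" is expected to overshoot observed
  occupancy: suitability excludes only water and elevation, so sensitivity
  (not specificity) is the meaningful score.
* The published skewness column for fitted kernels is not reproducible
  from the printed parameters by any moment formula we know; both analytic
  and sample skewness are provided, and neither is asserted against those
  printed values. Likewise the published local-Cauchy "mean distance" does
  not equal its printed location parameter and is treated as
  unreproducible.
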