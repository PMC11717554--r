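# trailspread

Settlements introduce plants; trails move them. `trailspread` is an R
package for reconstructing and simulating how a single introduction point
(a station) and linear corridors (hiking trails) shape the spread of a
plant across an Arctic coastal landscape, built for spatial ecologists
working with occurrence surveys, a DEM and trail geometry. Everything runs
on a synthetic study system shipped with the package, so the full pipeline
is testable without any field data.

## What it computes

**Establishment kernels.** From a transect abundance survey the package
builds establishment-distance samples under two source assumptions —
*local spread* (source = nearest other individual) and *trail spread*
(source = nearest individual on the trail) — and fits six candidate
distance distributions (log-normal, Cauchy, exponential, exponential
power, chi-square, Rayleigh; scipy-style `shape, location, scale`
parameters). Parameters are estimated by maximum likelihood; families are
ranked by histogram SSE with BIC as tie-breaker. Each fit reports the mean
establishment distance `E[Z]` (closed form where it exists; the median for
the mean-free Cauchy) and the skewness, whose large positive values flag
rare long-distance establishment.

**Stochastic spread simulation.** A yearly occupancy model on a 5-m grid:
the establishment probability surface is the FFT convolution of the
occupied state with the discretised kernel, `P_e(x, y) = sum_sources
pdf(z) * cell_size`, a cell establishes when `P_e > T_e` with
`T_e ~ U(0, 1)` drawn per cell and year, and water or cells above the
highest observed elevation (137 m) are unsuitable. Two scenarios are
compared: `no_trail_effect` (local kernel only) and `trail_effect` (trail
kernel additionally applied from occupied on-trail cells, combined as
`1 - (1 - P_local)(1 - P_trail)`). Runs are replicated with per-replicate
seeds and scored against survey records by sensitivity `TP / (TP + FA)`.

**Density attribution.** Gaussian-kernel density estimation of occurrence
records (Scott's rule), min–max normalised, regressed on z-scored distance
from the station, distance from the closest trail, elevation and the
station x trail interaction; reports adjusted (McFadden for Poisson) R²
and per-predictor partial R².

**Terrain preference.** Relative luminance (Rec. 709) of a 10-cm
orthomosaic as a gravel-vs-vegetation proxy, tested with a joint-shift
randomisation: all points translated rigidly by uniform shifts up to 10 m,
`p = #(medY_i >= medY_0) / n` over 1000 iterations including the observed
one.

## Worked example

```r
library(trailspread)

cfg    <- synth_config(seed = 1, n_rows = 200, n_cols = 200)
land   <- make_landscape(cfg)          # DEM, water, station, two trails
truth  <- simulate_truth(land, cfg)    # ground-truth occupancy 1928-2018
survey <- sample_transect_survey(truth, land, cfg)   # 2023-style survey

on_trail_share(survey)
#> [1] 86.3

tidy(rank_fits(distances_from_trail(survey)))[1:3, ]
#> # A tibble: 3 x 7
#>   family                 sse   bic params      mean_distance skewness assumption
#> 1 exponential_power 0.000240 3496. 1.3931, 11…          55.5    0.298 trail
#> 2 rayleigh          0.000291 3530. 7.9454, 38…          55.6    0.631 trail
#> 3 chi_square        0.000298 3560. 6.0982, 6.…          55.5    1.15  trail

# scenario comparison with the published kernels
fl <- kernel_fit("lognormal", c(0.8611, -0.0799, 1.3177), assumption = "local")
ft <- kernel_fit("lognormal", c(0.5760, -9.9562, 33.6560), assumption = "trail")
obs <- sample_systematic_survey(truth, 2014, block = 250)
h_trail <- run_simulation(land, fl, ft, "trail_effect", 1928, 2018,
                          land$station, n_replicates = 5, base_seed = 42)
h_local <- run_simulation(land, fl, NULL, "no_trail_effect", 1928, 2018,
                          land$station, n_replicates = 5, base_seed = 42)
sensitivity(h_trail, obs, 2014, 250)   # tp 10, fa 1, sensitivity 0.909
sensitivity(h_local, obs, 2014, 250)   # tp  4, fa 7, sensitivity 0.364

# terrain preference on the synthetic 10-cm orthomosaic
ortho <- render_luminance(land, head(survey, 80), cfg)
randomisation_test(ortho$occurrences, ortho$luminance, n = 1000, seed = 7)
#> <randomisation_result> observed median 0.7141 vs null median 0.3398
#>   (n = 1000), p = 0.001
```

Read it as: individuals concentrate on the trail (86.3% of individuals on
trail plots), off-trail individuals sit tens of metres from their nearest
on-trail source, the trail-effect scenario captures nearly all surveyed
presence blocks (sensitivity 0.91) where local-only spread reaches a third
of them (0.36), and the plants sit on markedly brighter (gravel) pixels
than the same pattern shifted at random (p = 0.001).

`autoplot()` methods exist for rasters, landscapes, density surfaces,
arrival maps and randomisation results; `tidy()`/`glance()` methods for
kernel rankings, the density GLM and the randomisation result. A thin CLI
(`inst/scripts/trailspread-cli.R`) wraps the same functions with
`synth` / `kernels` / `density` / `spread` / `terrain` subcommands.

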