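# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A small but full study system: landscape, truth run, transect survey.
small_config <- function(seed = 3) {
  synth_config(seed = seed, n_rows = 200, n_cols = 200)
}

small_system <- function() {
  fixture("small_system", function() {
    cfg <- small_config()
    ls <- make_landscape(cfg)
    truth <- simulate_truth(ls, cfg)
    survey <- sample_transect_survey(truth, ls, cfg)
    list(cfg = cfg, landscape = ls, truth = truth, survey = survey)
  })
}

# An occupancy_history with a prescribed single-replicate arrival matrix,
# for exercising samplers and sensitivity without running the simulator.
fake_history <- function(spec, arrival, start_year = 1928, end_year = 2018) {
  structure(
    list(spec = spec,
         arrival_year = list(raster_layer(spec, arrival)),
         mean_arrival = raster_layer(spec, arrival),
         n_colonised = raster_layer(spec, (!is.na(arrival)) * 1),
         scenario = "no_trail_effect", start_year = start_year,
         end_year = end_year, n_replicates = 1, base_seed = 0),
    class = "occupancy_history")
}

# Independent point-to-segment distance, deliberately re-derived for use as
# a brute-force oracle.
oracle_point_segment_dist <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  L2 <- vx^2 + vy^2
  if (L2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- ((px - ax) * vx + (py - ay) * vy) / L2
  t <- min(1, max(0, t))
  sqrt((px - ax - t * vx)^2 + (py - ay - t * vy)^2)
}

# The bright gravel bar fixture for the terrain test: a 2 x 8 m bright bar
# (luminance 0.9) centred at (15, 15) in a 30 x 30 m dark background at
# 10-cm resolution.
gravel_bar_luminance <- function() {
  fixture("gravel_bar", function() {
    spec <- grid_spec(0, 0, 0.1, 300, 300)
    xs <- (1:300 - 0.5) * 0.1
    bar <- outer(abs(xs - 15) <= 4, abs(xs - 15) <= 1, `&`)
    v <- matrix(0.2, 300, 300)
    v[bar] <- 0.9
    raster_layer(spec, v)
  })
}

points_on_bar <- function(seed, n = 30) {
  set.seed(seed)
  data.frame(x = stats::runif(n, 14.2, 15.8), y = stats::runif(n, 11.8, 18.2))
}

# Classical R2 of a gaussian glm, for cross-checking partial_r2.
model_r2_for_test <- function(fit) {
  y <- fit$model[[1]]
  1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
}
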