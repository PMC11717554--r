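#' Configuration for the synthetic landscape and surveys
#'
#' Bundles every knob of the synthetic data generator. The defaults are the
#' study conditions the rest of the package is exercised under: a 2 x 2 km
#' coastal strandflat at 5-m resolution, true establishment kernels equal to
#' the best fitted local (three-parameter log-normal, mean ~1.8 m) and
#' trail (three-parameter log-normal, mean ~29.8 m) kernels, a 1928-2018
#' simulation period with landscape surveys in 1994/2014/2018 and a
#' transect abundance survey in 2023, and an on-trail share of individuals
#' of 86.9%.
#'
#' @param seed Integer seed; all generator outputs are pure functions of
#'   the configuration including this seed.
#' @param n_rows,n_cols,cell_size Grid dimensions (cells) and resolution
#'   (m).
#' @param true_local_kernel,true_trail_kernel Lists with `family` and
#'   `params` defining the generating kernels.
#' @param terrain_preference_strength Log-linear preference of individuals
#'   for bright (gravel) pixels in the synthetic orthomosaic; 0 = no
#'   terrain association.
#' @param on_trail_share Expected share of transect-survey individuals that
#'   fall on trail plots.
#' @param mean_abundance Mean extra individuals per occupied off-trail
#'   sampling point (Poisson).
#' @param survey_years Years of the systematic landscape surveys.
#' @param start_year,end_year Simulated period.
#' @param transect_year Year of the transect abundance survey.
#' @param n_lakes_range Range of the number of random lakes.
#' @param ortho_res,ortho_margin Orthomosaic resolution and margin (m).
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1,
                         n_rows = 400, n_cols = 400, cell_size = 5,
                         true_local_kernel = list(
                           family = "lognormal",
                           params = c(0.8611, -0.0799, 1.3177)),
                         true_trail_kernel = list(
                           family = "lognormal",
                           params = c(0.5760, -9.9562, 33.6560)),
                         terrain_preference_strength = 6,
                         on_trail_share = 0.869,
                         mean_abundance = 3,
                         survey_years = c(1994, 2014, 2018),
                         start_year = 1928, end_year = 2018,
                         transect_year = 2023,
                         n_lakes_range = c(2, 5),
                         ortho_res = 0.1, ortho_margin = 15) {
  stopifnot(seed == as.integer(seed), n_rows >= 50, n_cols >= 50,
            terrain_preference_strength >= 0,
            on_trail_share > 0, on_trail_share < 1)
  structure(as.list(environment()), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("<synth_config> seed %d, %dx%d cells @ %g m, %d-%d\n",
              x$seed, x$n_rows, x$n_cols, x$cell_size,
              x$start_year, x$end_year))
  invisible(x)
}

true_kernel_fit <- function(k, assumption) {
  kernel_fit(k$family, k$params, assumption = assumption)
}

#' Generate a synthetic coastal landscape
#'
#' Builds a strandflat-like landscape: sea along the north edge behind a
#' wiggling coastline, elevation rising inland with superimposed raised
#' beach ridges parallel to the coast plus a smooth random field, 2-5 lakes
#' on low ground, a station on land near the coast, and two trails starting
#' at the station — "east" following the coastline and "south" heading
#' inland across the ridges.
#'
#' @param config A [synth_config()].
#' @return A `landscape_bundle`: `dem`, `water_mask`, `trail_mask`,
#'   `trails` (tibble), `station` (`c(x, y)`), `spec`, plus the internal
#'   terrain parameters reused by [render_luminance()].
#' @export
make_landscape <- function(config = synth_config()) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(config$seed)
  spec <- grid_spec(0, 0, config$cell_size, config$n_rows, config$n_cols)
  Lx <- spec$n_cols * spec$cell_size
  Ly <- spec$n_rows * spec$cell_size
  xs <- cell_centres_x(spec)
  ys <- cell_centres_y(spec)
  X <- matrix(xs, spec$n_rows, spec$n_cols, byrow = TRUE)
  Y <- matrix(ys, spec$n_rows, spec$n_cols)

  coast_amp <- 0.03 * Ly
  coast_phase <- stats::runif(1, 0, 2 * pi)
  coast_y <- function(x) 0.88 * Ly + coast_amp * sin(2 * pi * x / (0.45 * Lx) + coast_phase)
  inland <- coast_y(X) - Y                     # metres inland of the coastline
  ridge_wavelength <- 200
  dem <- 0.06 * inland +
    5 * sin(2 * pi * inland / ridge_wavelength) * exp(-pmax(inland, 0) / 1500)
  # smooth random field: a handful of long-wavelength cosine waves
  for (k in 1:6) {
    wl <- stats::runif(1, 300, 1500)
    th <- stats::runif(1, 0, pi)
    ph <- stats::runif(1, 0, 2 * pi)
    dem <- dem + 1.5 * cos(2 * pi * (X * cos(th) + Y * sin(th)) / wl + ph)
  }
  sea <- dem <= 0
  dem <- pmin(pmax(dem, 0), 150)
  water <- sea

  n_lakes <- sample(seq(config$n_lakes_range[1], config$n_lakes_range[2]), 1)
  low <- which(!sea & dem > 1 & dem < 35, arr.ind = TRUE)
  for (l in seq_len(n_lakes)) {
    c_idx <- low[sample(nrow(low), 1), ]
    cx <- xs[c_idx[2]]; cy <- ys[c_idx[1]]
    rad <- stats::runif(1, 30, 80)
    lake <- (X - cx)^2 + (Y - cy)^2 <= rad^2 & dem <= 50
    water <- water | lake
  }

  # station: land cell nearest to a target just inland of the coast
  target <- c(0.25 * Lx, coast_y(0.25 * Lx) - 60)
  land <- which(!water & dem > 1 & dem < 40, arr.ind = TRUE)
  d2 <- (xs[land[, 2]] - target[1])^2 + (ys[land[, 1]] - target[2])^2
  st_cell <- land[which.min(d2), ]
  station <- c(xs[st_cell[2]], ys[st_cell[1]])

  south_y <- seq(station[2], 0.08 * Ly, by = -50)
  south <- tibble::tibble(
    trail = "south",
    x = pmin(pmax(station[1] + 40 * sin(2 * pi * (station[2] - south_y) / 1500),
                  0.05 * Lx), 0.95 * Lx),
    y = south_y)
  south$x[1] <- station[1]   # trailhead at the station
  east_x <- seq(station[1], 0.92 * Lx, by = 50)
  east <- tibble::tibble(trail = "east", x = east_x,
                         y = pmin(coast_y(east_x) - 60, Ly * 0.86))
  east$x[1] <- station[1]; east$y[1] <- station[2]
  trails <- dplyr::bind_rows(south, east)

  structure(
    list(spec = spec,
         dem = raster_layer(spec, dem),
         water_mask = raster_layer(spec, water),
         trail_mask = rasterize_trail(spec, trails, width = 2 * spec$cell_size),
         trails = trails, station = station,
         terrain = list(coast_y = coast_y, ridge_wavelength = ridge_wavelength)),
    class = "landscape_bundle")
}

#' @export
print.landscape_bundle <- function(x, ...) {
  cat(sprintf("<landscape_bundle> %s, %.0f%% water, station (%g, %g), trails: %s\n",
              format(x$spec), 100 * mean(x$water_mask$values),
              x$station[1], x$station[2],
              paste(unique(x$trails$trail), collapse = ", ")))
  invisible(x)
}

#' Simulate the ground-truth occupancy history
#'
#' Runs the spread simulator under the trail-effect scenario with the
#' configuration's true kernels, initialised at the station in
#' `config$start_year` — the closed-loop truth against which surveys are
#' sampled and parameter recovery is judged.
#'
#' @param landscape A `landscape_bundle`.
#' @param config A [synth_config()].
#' @param n_replicates Replicates of the truth run (default 1).
#' @return An `occupancy_history`.
#' @export
simulate_truth <- function(landscape, config = synth_config(),
                           n_replicates = 1) {
  run_simulation(
    landscape,
    fit_local = true_kernel_fit(config$true_local_kernel, "local"),
    fit_trail = true_kernel_fit(config$true_trail_kernel, "trail"),
    scenario = "trail_effect",
    start_year = config$start_year, end_year = config$end_year,
    init_point = landscape$station,
    n_replicates = n_replicates, base_seed = config$seed * 13 + 1,
    elevation_limit = 137)
}

#' Systematic 1-km landscape survey of the truth
#'
#' Emulates the gridded presence surveys: the area is divided into square
#' blocks and every block containing at least one (replicate-majority)
#' occupied cell by the survey year yields one presence record at the block
#' centre, tagged `systematic_grid`.
#'
#' @param truth An `occupancy_history`.
#' @param year Survey year.
#' @param block Block side (m), default 1000.
#' @return An occurrence tibble (possibly empty).
#' @export
sample_systematic_survey <- function(truth, year, block = 1000) {
  stopifnot(year >= truth$start_year, year <= truth$end_year)
  spec <- truth$spec
  occ <- majority_occupied(truth, year)
  cells <- which(occ, arr.ind = TRUE)
  if (nrow(cells) == 0) {
    return(occurrences(numeric(0), numeric(0), integer(0), integer(0),
                       character(0)))
  }
  cx <- spec$origin_x + (cells[, 2] - 0.5) * spec$cell_size
  cy <- spec$origin_y + (cells[, 1] - 0.5) * spec$cell_size
  bx <- floor((cx - spec$origin_x) / block)
  by <- floor((cy - spec$origin_y) / block)
  blocks <- unique(cbind(bx, by))
  occurrences(
    x = spec$origin_x + (blocks[, 1] + 0.5) * block,
    y = spec$origin_y + (blocks[, 2] + 0.5) * block,
    year = year, abundance = 1, plot_class = "systematic_grid")
}

#' Survey protocol for the T-shaped transects
#'
#' @param transect_spacing Spacing between transects along the trail (m).
#' @param plot_length Trail-plot length along the trail (m).
#' @param plot_width Plot width (m).
#' @param off_trail_length Length of the perpendicular off-trail plot (m).
#' @param stop_rule Consecutive empty trail plots after which the survey
#'   stops.
#' @param off_trail_side Side of the trail surveyed (`"east"`: a protected
#'   bird reserve rules out the west side).
#' @return A `survey_protocol` list.
#' @export
survey_protocol <- function(transect_spacing = 50, plot_length = 50,
                            plot_width = 2, off_trail_length = 100,
                            stop_rule = 5, off_trail_side = "east") {
  stopifnot(transect_spacing > 0, plot_length > 0, plot_width > 0,
            off_trail_length > 0, stop_rule >= 1,
            off_trail_side == "east")
  structure(as.list(environment()), class = "survey_protocol")
}

# Arc-length resampling of a polyline: position and unit tangent at s.
polyline_point <- function(verts, s) {
  seg <- diff(verts)
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  s <- min(max(s, 0), cum[length(cum)])
  i <- max(which(cum <= s + 1e-9))
  i <- min(i, nrow(seg))
  t <- (s - cum[i]) / len[i]
  list(p = verts[i, ] + t * seg[i, ], tangent = seg[i, ] / len[i])
}

#' Sample a T-shaped transect abundance survey along the south trail
#'
#' Walks the "south" trail from the trailhead, placing a T-shaped transect
#' every `transect_spacing` metres: a 2 x 50 m plot on the trail and a
#' perpendicular 2 x 100 m off-trail plot extending eastward from the
#' middle of the trail plot. Each occupied truth cell whose centre falls
#' inside a plot holds `1 + Poisson(lambda)` individuals scattered
#' uniformly within the cell; individuals are then aggregated at the 50-cm
#' GPS recording resolution into records carrying abundance counts. The
#' trail-cell lambda is calibrated so the expected share of individuals on
#' trail plots equals `config$on_trail_share`. Detection within plots is
#' perfect. Surveying stops once `stop_rule` consecutive trail plots are
#' empty.
#'
#' @param truth An `occupancy_history` (evaluated at its final year).
#' @param landscape A `landscape_bundle` with a "south" trail.
#' @param config A [synth_config()].
#' @param protocol A [survey_protocol()].
#' @param seed RNG seed for the abundance draws.
#' @return An occurrence tibble with `plot_class` in `{trail, off_trail}`.
#' @export
sample_transect_survey <- function(truth, landscape,
                                   config = synth_config(),
                                   protocol = survey_protocol(),
                                   seed = config$seed + 101) {
  verts <- as.matrix(landscape$trails[landscape$trails$trail == "south",
                                      c("x", "y")])
  if (nrow(verts) < 2) stop("'south' trail missing or too short")
  total_len <- sum(sqrt(rowSums(diff(verts)^2)))
  if (total_len < 3 * protocol$transect_spacing) {
    stop("'south' trail too short for the transect protocol")
  }
  spec <- truth$spec
  occ <- majority_occupied(truth, truth$end_year)
  cells <- which(occ, arr.ind = TRUE)
  cell_x <- spec$origin_x + (cells[, 2] - 0.5) * spec$cell_size
  cell_y <- spec$origin_y + (cells[, 1] - 0.5) * spec$cell_size

  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)

  half_w <- protocol$plot_width / 2
  transects <- list()
  s <- 0; empty_streak <- 0; t_id <- 0
  while (s + protocol$plot_length <= total_len &&
         empty_streak < protocol$stop_rule) {
    t_id <- t_id + 1
    pp <- polyline_point(verts, s)
    u <- pp$tangent
    v <- c(u[2], -u[1])          # perpendicular
    if (v[1] < 0) v <- -v        # eastward (positive x component)
    rel_x <- cell_x - pp$p[1]; rel_y <- cell_y - pp$p[2]
    pu <- rel_x * u[1] + rel_y * u[2]
    pv <- rel_x * v[1] + rel_y * v[2]
    on_plot <- pu >= 0 & pu <= protocol$plot_length & abs(pv) <= half_w
    mid <- protocol$plot_length / 2
    off_plot <- !on_plot & abs(pu - mid) <= half_w &
      pv > half_w & pv <= half_w + protocol$off_trail_length
    transects[[t_id]] <- list(id = t_id, on = which(on_plot),
                              off = which(off_plot))
    empty_streak <- if (any(on_plot)) 0 else empty_streak + 1
    s <- s + protocol$transect_spacing
  }

  n_on <- sum(lengths(lapply(transects, `[[`, "on")))
  n_off <- sum(lengths(lapply(transects, `[[`, "off")))
  lambda_off <- config$mean_abundance
  # calibrate the per-cell individual count on trail plots so the expected
  # share of individuals on the trail matches config$on_trail_share
  p <- config$on_trail_share
  lambda_on <- if (n_on > 0) {
    max(0, p / (1 - p) * n_off * (1 + lambda_off) / n_on - 1)
  } else lambda_off
  half_c <- spec$cell_size / 2
  # scatter m individuals inside an occupied cell, then aggregate them at
  # the 50-cm GPS recording resolution into records with abundance counts
  sample_cells <- function(cells_idx, lambda, cls, t_id) {
    if (length(cells_idx) == 0) return(NULL)
    out <- list()
    for (ci in cells_idx) {
      m <- 1 + stats::rpois(1, lambda)
      px <- cell_x[ci] + stats::runif(m, -half_c, half_c)
      py <- cell_y[ci] + stats::runif(m, -half_c, half_c)
      key <- paste(round(px / 0.5), round(py / 0.5))
      agg <- tapply(seq_len(m), key, identity, simplify = FALSE)
      out[[length(out) + 1]] <- tibble::tibble(
        x = vapply(agg, function(ix) mean(px[ix]), numeric(1)),
        y = vapply(agg, function(ix) mean(py[ix]), numeric(1)),
        abundance = lengths(agg), plot_class = cls, transect = t_id)
    }
    dplyr::bind_rows(out)
  }
  rows <- list()
  for (tr in transects) {
    rows[[length(rows) + 1]] <- sample_cells(tr$on, lambda_on, "trail", tr$id)
    rows[[length(rows) + 1]] <- sample_cells(tr$off, lambda_off, "off_trail", tr$id)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    out <- occurrences(numeric(0), numeric(0), integer(0), integer(0),
                       character(0))
    out$transect <- integer(0)
    return(out)
  }
  df <- dplyr::bind_rows(rows)
  out <- occurrences(df$x, df$y, config$transect_year, df$abundance,
                     df$plot_class)
  out$transect <- df$transect
  out
}

#' Render a synthetic 10-cm orthomosaic and place occurrences on it
#'
#' Builds a fine-resolution luminance raster over the bounding box of the
#' given occurrences (plus a margin): a dark vegetated background with
#' smooth spatial variation and pixel noise, a bright gravel band along the
#' trail, and brighter raised-beach ridge crests. Each occurrence is then
#' re-placed at a pixel drawn within 3 m of its original position with
#' probability proportional to `exp(strength * luminance)`, so
#' `terrain_preference_strength = 0` yields no terrain association and
#' large values snap individuals onto bright gravel. The RGB companion
#' raster is constructed so that Rec. 709 relative luminance recovers the
#' luminance channel exactly (grey gravel, luminance-scaled green
#' vegetation).
#'
#' @param landscape A `landscape_bundle`.
#' @param occurrences Occurrence tibble within the landscape.
#' @param config A [synth_config()].
#' @param seed RNG seed.
#' @return A list with `luminance` (`spread_raster`), `rgb`
#'   (`rgb_raster`) and `occurrences` (re-placed points).
#' @export
render_luminance <- function(landscape, occurrences,
                             config = synth_config(),
                             seed = config$seed + 202) {
  stopifnot(nrow(occurrences) >= 1)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  res <- config$ortho_res
  m <- config$ortho_margin
  x0 <- floor((min(occurrences$x) - m) / res) * res
  y0 <- floor((min(occurrences$y) - m) / res) * res
  nc <- ceiling((max(occurrences$x) + m - x0) / res)
  nr <- ceiling((max(occurrences$y) + m - y0) / res)
  spec <- grid_spec(x0, y0, res, nr, nc)
  xs <- cell_centres_x(spec); ys <- cell_centres_y(spec)
  X <- matrix(xs, nr, nc, byrow = TRUE)
  Y <- matrix(ys, nr, nc)

  lum <- 0.22 +
    0.05 * cos(2 * pi * X / 37) * cos(2 * pi * Y / 53) +
    matrix(stats::rnorm(nr * nc, 0, 0.02), nr, nc)
  # brighter raised-beach ridge crests (same ridge field as the DEM)
  inland <- landscape$terrain$coast_y(X) - Y
  crest <- sin(2 * pi * inland / landscape$terrain$ridge_wavelength)
  lum <- lum + 0.18 * pmax(crest - 0.7, 0) / 0.3
  # bright gravel band along the trails
  tl <- trails_as_list(landscape$trails)
  dist_trail <- rep(Inf, length(X))
  for (t in tl) dist_trail <- pmin(dist_trail,
                                   segment_min_dist(as.vector(X), as.vector(Y), t))
  dist_trail <- matrix(dist_trail, nr, nc)
  on_trail <- dist_trail <= 1
  lum[on_trail] <- 0.72 + stats::rnorm(sum(on_trail), 0, 0.03)
  lum <- pmin(pmax(lum, 0), 1)

  # re-place each occurrence with terrain preference
  strength <- config$terrain_preference_strength
  radius <- 3
  rpix <- ceiling(radius / res)
  newx <- occurrences$x; newy <- occurrences$y
  for (i in seq_len(nrow(occurrences))) {
    cc <- points_to_cells(occurrences[i, ], spec)
    if (!cc$inside) next
    rows <- pmax(1, cc$row - rpix):pmin(nr, cc$row + rpix)
    cols <- pmax(1, cc$col - rpix):pmin(nc, cc$col + rpix)
    sub <- as.matrix(expand.grid(row = rows, col = cols))
    d2 <- (ys[sub[, 1]] - occurrences$y[i])^2 +
      (xs[sub[, 2]] - occurrences$x[i])^2
    sub <- sub[d2 <= radius^2, , drop = FALSE]
    w <- exp(strength * lum[sub])
    pick <- sub[sample(nrow(sub), 1, prob = w), ]
    newx[i] <- xs[pick[2]] + stats::runif(1, -res / 2, res / 2)
    newy[i] <- ys[pick[1]] + stats::runif(1, -res / 2, res / 2)
  }
  occ <- occurrences
  occ$x <- newx; occ$y <- newy

  # RGB: grey gravel where bright, luminance-matched green vegetation
  veg_base <- c(0.35, 0.62, 0.28)
  veg_lum <- sum(veg_base * c(0.2126, 0.7152, 0.0722))
  rgb_arr <- array(0, c(nr, nc, 3))
  gravel <- lum >= 0.5
  for (ch in 1:3) {
    band <- lum * (veg_base[ch] / veg_lum)
    band[gravel] <- lum[gravel]
    rgb_arr[, , ch] <- band
  }
  list(luminance = raster_layer(spec, lum),
       rgb = rgb_raster(spec, pmin(rgb_arr, 1)),
       occurrences = occ)
}
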