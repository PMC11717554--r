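#' Altitudinal establishment threshold from observations
#'
#' The upper elevation limit for establishment is set at the highest
#' elevation at which the species was ever observed (the DEM value sampled
#' at the occurrence locations).
#'
#' @param occ Occurrence tibble.
#' @param dem Elevation raster (m a.s.l.).
#' @return Threshold elevation in metres.
#' @export
elevation_threshold <- function(occ, dem) {
  cells <- points_to_cells(occ, dem$spec)
  ok <- cells$inside
  if (any(!ok)) warning(sum(!ok), " occurrence(s) outside the DEM ignored")
  elev <- dem$values[cbind(cells$row[ok], cells$col[ok])]
  elev <- elev[!is.na(elev)]
  if (length(elev) == 0) stop("no occurrence falls on a valid DEM cell")
  max(elev)
}

#' Build the establishment suitability mask
#'
#' A cell is suitable iff it is not water (sea or lake) and its elevation
#' does not exceed the altitudinal threshold. Nodata elevation cells are
#' unsuitable.
#'
#' @param dem Elevation raster.
#' @param water_mask Logical raster of sea/lake cells.
#' @param threshold Elevation threshold (m), e.g. from
#'   [elevation_threshold()].
#' @return A logical `spread_raster`.
#' @export
build_suitability <- function(dem, water_mask, threshold) {
  if (!same_spec(dem$spec, water_mask$spec)) {
    stop("dem and water_mask are on different grids")
  }
  ok <- !water_mask$values & !is.na(dem$values) & dem$values <= threshold
  raster_layer(dem$spec, ok)
}

#' Discretise a fitted kernel onto the simulation grid
#'
#' Builds the `(2r+1) x (2r+1)` weight stencil used in the convolution: the
#' weight of an offset cell at distance `z` between cell centres is
#' `pdf(z) * cell_size`, i.e. the fitted 1-D distance density interpreted as
#' a per-cell, per-year establishment probability along any bearing (no
#' ring correction by default; set `ring_correction = TRUE` to divide by the
#' ring circumference `2 pi z` and renormalise the 2-D mass). The centre
#' cell is evaluated at `z = cell_size / 2` so families with a pole at zero
#' stay finite. The truncation radius is the distance quantile
#' `truncation_q` in cells; heavy-tailed families whose quantile explodes
#' are capped at `max_radius` cells with a warning. If the stencil mass
#' exceeds 1 it is rescaled to sum to 1.
#'
#' @param fit A `kernel_fit`.
#' @param cell_size Grid cell size (m), default 5.
#' @param truncation_q Quantile at which the kernel is truncated, in
#'   (0.9, 1). Default 0.99.
#' @param max_radius Hard cap on the stencil radius in cells.
#' @param ring_correction Apply the `1 / (2 pi z)` area correction.
#' @return A `discrete_kernel`: list with `weights`, `radius`, `cell_size`,
#'   `assumption`.
#' @export
discretize_kernel <- function(fit, cell_size = 5, truncation_q = 0.99,
                              max_radius = 100L, ring_correction = FALSE) {
  stopifnot(truncation_q > 0.9, truncation_q < 1)
  fam <- kernel_family(fit$family)
  qd <- fam$quantile(truncation_q, fit$params)
  r <- ceiling(qd / cell_size)
  if (!is.finite(r) || r > max_radius) {
    warning(sprintf("truncation radius for %s capped at %d cells", fit$family,
                    max_radius))
    r <- max_radius
  }
  r <- max(1L, as.integer(r))
  off <- (-r):r
  z <- sqrt(outer(off^2, off^2, `+`)) * cell_size
  z[r + 1, r + 1] <- cell_size / 2
  w <- matrix(fam$pdf(as.vector(z), fit$params) * cell_size,
              nrow(z), ncol(z))
  if (ring_correction) {
    w <- w / (2 * pi * z) * cell_size^2
  }
  w[w < 0 | !is.finite(w)] <- 0
  s <- sum(w)
  if (s > 1) w <- w / s
  structure(list(weights = w, radius = r, cell_size = cell_size,
                 assumption = fit$assumption, family = fit$family),
            class = "discrete_kernel")
}

#' @export
print.discrete_kernel <- function(x, ...) {
  cat(sprintf("<discrete_kernel> %s, radius %d cells (%g m), mass %.3f\n",
              x$family, x$radius, x$radius * x$cell_size, sum(x$weights)))
  invisible(x)
}

# 2-D linear convolution of a state matrix with a centred (2r+1)^2 stencil,
# evaluated over the state's own extent (zero-padded boundary), via FFT.
fft_convolve <- function(state, weights) {
  n_r <- nrow(state); n_c <- ncol(state)
  k_r <- nrow(weights); k_c <- ncol(weights)
  if (k_r > 2 * n_r - 1 || k_c > 2 * n_c - 1) stop("kernel larger than grid")
  fft_convolve_planned(state, make_fft_plan(dim(state), dim(weights), weights))
}

# Precompute the padded kernel FFT once per simulation.
make_fft_plan <- function(state_dim, kernel_dim, weights) {
  pr <- stats::nextn(state_dim[1] + kernel_dim[1] - 1L)
  pc <- stats::nextn(state_dim[2] + kernel_dim[2] - 1L)
  K <- matrix(0, pr, pc)
  K[seq_len(kernel_dim[1]), seq_len(kernel_dim[2])] <- weights
  r <- (kernel_dim[1] - 1L) / 2L
  list(pr = pr, pc = pc, fK = stats::fft(K), r = r,
       n_r = state_dim[1], n_c = state_dim[2])
}

fft_convolve_planned <- function(state, plan) {
  S <- matrix(0, plan$pr, plan$pc)
  S[seq_len(plan$n_r), seq_len(plan$n_c)] <- state
  full <- Re(stats::fft(stats::fft(S) * plan$fK, inverse = TRUE)) /
    (plan$pr * plan$pc)
  out <- full[plan$r + seq_len(plan$n_r), plan$r + seq_len(plan$n_c)]
  out[out < 0] <- 0   # FFT round-off
  out
}

# Direct nested-loop convolution; the independent oracle for fft_convolve.
direct_convolve <- function(state, weights) {
  r <- (nrow(weights) - 1L) / 2L
  n_r <- nrow(state); n_c <- ncol(state)
  out <- matrix(0, n_r, n_c)
  idx <- which(state != 0, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    for (di in (-r):r) {
      ii <- i + di
      if (ii < 1 || ii > n_r) next
      for (dj in (-r):r) {
        jj <- j + dj
        if (jj < 1 || jj > n_c) next
        out[ii, jj] <- out[ii, jj] + state[i, j] * weights[di + r + 1, dj + r + 1]
      }
    }
  }
  out
}

#' Yearly establishment probability surface
#'
#' Convolves the occupied-cell state with the discretised establishment
#' kernel(s). Under the `"no_trail_effect"` scenario only the local kernel
#' applies, from every occupied source cell. Under `"trail_effect"` the
#' trail kernel additionally applies from occupied cells lying on the
#' trail, and the two per-source probabilities combine as independent
#' sources: `P_e = 1 - (1 - min(P_local, 1)) * (1 - min(P_trail, 1))`.
#'
#' @param state Logical occupancy raster (or matrix).
#' @param kernel_local Local-spread `discrete_kernel`.
#' @param kernel_trail Trail-spread `discrete_kernel` or `NULL`.
#' @param trail_mask Logical on-trail raster; required for `trail_effect`.
#' @param scenario `"no_trail_effect"` or `"trail_effect"`.
#' @return A numeric `spread_raster` of establishment probabilities in
#'   `[0, 1]` (a plain matrix when `state` is a matrix).
#' @export
establishment_probability <- function(state, kernel_local,
                                      kernel_trail = NULL, trail_mask = NULL,
                                      scenario = c("no_trail_effect",
                                                   "trail_effect")) {
  scenario <- match.arg(scenario)
  is_raster <- inherits(state, "spread_raster")
  sm <- if (is_raster) state$values else state
  p_local <- pmin(fft_convolve(sm * 1, kernel_local$weights), 1)
  if (scenario == "trail_effect") {
    if (is.null(kernel_trail) || is.null(trail_mask)) {
      stop("trail_effect needs both kernel_trail and trail_mask")
    }
    tm <- if (inherits(trail_mask, "spread_raster")) trail_mask$values else trail_mask
    p_trail <- pmin(fft_convolve((sm & tm) * 1, kernel_trail$weights), 1)
    p <- 1 - (1 - p_local) * (1 - p_trail)
  } else {
    p <- p_local
  }
  p <- pmin(pmax(p, 0), 1)
  if (is_raster) raster_layer(state$spec, p) else p
}

#' Advance the occupancy state by one year
#'
#' Each unoccupied suitable cell draws an independent uniform establishment
#' threshold `T_e ~ U(0, 1)` and becomes occupied iff `P_e > T_e`
#' (equivalently, a Bernoulli(`P_e`) trial). Occupied cells never revert;
#' unsuitable cells are never occupied.
#'
#' @param state Logical occupancy matrix.
#' @param p_e Establishment probability matrix.
#' @param suitability Logical suitability matrix.
#' @return The next logical occupancy matrix. Consumes RNG draws.
#' @export
step_year <- function(state, p_e, suitability) {
  stopifnot(all(dim(state) == dim(p_e)), all(dim(state) == dim(suitability)))
  t_e <- matrix(stats::runif(length(state)), nrow(state), ncol(state))
  state | (suitability & !state & (p_e > t_e))
}

#' Run the stochastic spread simulation
#'
#' Iterates yearly establishment from a single initial occurrence over
#' `start_year:end_year`, recording per cell the first year of
#' establishment, for `n_replicates` independent replicates (replicate `k`
#' is seeded with `base_seed + k`, so histories are bit-reproducible).
#'
#' @param landscape A `landscape_bundle` (see [make_landscape()]), or any
#'   list with `dem`, `water_mask`, `trails`, `spec` and optionally
#'   `trail_mask`.
#' @param fit_local Local-spread `kernel_fit`.
#' @param fit_trail Trail-spread `kernel_fit` (required for
#'   `scenario = "trail_effect"`).
#' @param scenario `"no_trail_effect"` or `"trail_effect"`.
#' @param start_year,end_year Simulated period (e.g. 1928 and 2018).
#' @param init_point `c(x, y)` of the first historical record.
#' @param n_replicates Number of replicate runs (default 10).
#' @param base_seed Integer base seed.
#' @param elevation_limit Suitability threshold (m); default 137, the
#'   highest recorded observation elevation.
#' @param truncation_q,max_radius,ring_correction Passed to
#'   [discretize_kernel()].
#' @return An `occupancy_history`: per-replicate `arrival_year` rasters
#'   (sentinel `NA` = never colonised), the replicate-averaged
#'   `mean_arrival` raster, a `n_colonised` raster counting colonising
#'   replicates, and run metadata.
#' @export
run_simulation <- function(landscape, fit_local, fit_trail = NULL,
                           scenario = c("no_trail_effect", "trail_effect"),
                           start_year = 1928, end_year = 2018,
                           init_point, n_replicates = 10, base_seed = 1,
                           elevation_limit = 137,
                           truncation_q = 0.99, max_radius = 100L,
                           ring_correction = FALSE) {
  scenario <- match.arg(scenario)
  spec <- landscape$spec
  suit <- build_suitability(landscape$dem, landscape$water_mask,
                            elevation_limit)$values
  init <- points_to_cells(tibble::tibble(x = as_xy(init_point)[1],
                                         y = as_xy(init_point)[2]), spec)
  if (!init$inside) stop("init_point lies outside the grid")
  if (!suit[init$row, init$col]) stop("init_point cell is unsuitable")

  k_local <- discretize_kernel(fit_local, spec$cell_size, truncation_q,
                               max_radius, ring_correction)
  plan_local <- make_fft_plan(dim(suit), dim(k_local$weights), k_local$weights)
  plan_trail <- NULL; trail_mask <- NULL
  if (scenario == "trail_effect") {
    if (is.null(fit_trail)) stop("trail_effect needs fit_trail")
    k_trail <- discretize_kernel(fit_trail, spec$cell_size, truncation_q,
                                 max_radius, ring_correction)
    plan_trail <- make_fft_plan(dim(suit), dim(k_trail$weights), k_trail$weights)
    trail_mask <- if (!is.null(landscape$trail_mask)) landscape$trail_mask$values
                  else rasterize_trail(spec, landscape$trails)$values
  }

  years <- start_year:end_year
  arrivals <- vector("list", n_replicates)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  for (rep_i in seq_len(n_replicates)) {
    set.seed(base_seed + rep_i)
    state <- matrix(FALSE, spec$n_rows, spec$n_cols)
    state[init$row, init$col] <- TRUE
    arrival <- matrix(NA_real_, spec$n_rows, spec$n_cols)
    arrival[init$row, init$col] <- start_year
    for (yr in years[-1]) {
      p <- pmin(fft_convolve_planned(state * 1, plan_local), 1)
      if (scenario == "trail_effect") {
        p_t <- pmin(fft_convolve_planned((state & trail_mask) * 1, plan_trail), 1)
        p <- 1 - (1 - p) * (1 - p_t)
      }
      new_state <- step_year(state, p, suit)
      arrival[new_state & !state] <- yr
      state <- new_state
    }
    arrivals[[rep_i]] <- arrival
  }
  arr_stack <- simplify2array(arrivals)
  mean_arrival <- apply(arr_stack, c(1, 2), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  n_col <- apply(!is.na(arr_stack), c(1, 2), sum)
  structure(
    list(spec = spec,
         arrival_year = lapply(arrivals, raster_layer, spec = spec),
         mean_arrival = raster_layer(spec, mean_arrival),
         n_colonised = raster_layer(spec, n_col),
         scenario = scenario, start_year = start_year, end_year = end_year,
         n_replicates = n_replicates, base_seed = base_seed),
    class = "occupancy_history")
}

#' @export
print.occupancy_history <- function(x, ...) {
  occ <- mean(vapply(x$arrival_year, function(a) sum(!is.na(a$values)),
                     numeric(1)))
  cat(sprintf("<occupancy_history> %s, %d-%d, %d replicate(s), mean %d cells colonised\n",
              x$scenario, x$start_year, x$end_year, x$n_replicates,
              round(occ)))
  invisible(x)
}

# Cells occupied by a given year in a majority of replicates.
majority_occupied <- function(history, year) {
  by_year <- vapply(history$arrival_year,
                    function(a) a$values <= year & !is.na(a$values),
                    matrix(TRUE, history$spec$n_rows, history$spec$n_cols))
  apply(by_year, c(1, 2), sum) > length(history$arrival_year) / 2
}

#' Evaluate simulated spread against observed presences
#'
#' Presence-only evaluation of the simulated extent: each observed presence
#' is aggregated to an evaluation block (default 1000 m, the systematic
#' survey unit; use the cell size for point records) and counts as a true
#' presence (TP) if any replicate-majority-occupied cell falls in its block
#' by the survey year, otherwise as a false absence (FA). Sensitivity is
#' `TP / (TP + FA)`.
#'
#' @param history An `occupancy_history`.
#' @param observations Occurrence tibble of presences for one survey year.
#' @param year Survey year to evaluate at (default: the most common
#'   observation year).
#' @param eval_block Block side length (m).
#' @return A one-row tibble with `year`, `tp`, `fa`, `sensitivity`.
#' @export
sensitivity <- function(history, observations, year = NULL,
                        eval_block = 1000) {
  if (nrow(observations) == 0) stop("no observations to evaluate")
  if (is.null(year)) {
    year <- as.integer(names(sort(table(observations$year), decreasing = TRUE))[1])
  }
  spec <- history$spec
  occ <- majority_occupied(history, year)
  cells <- which(occ, arr.ind = TRUE)
  block_of <- function(x, y) {
    paste(floor((x - spec$origin_x) / eval_block),
          floor((y - spec$origin_y) / eval_block))
  }
  occ_blocks <- unique(block_of(
    spec$origin_x + (cells[, 2] - 0.5) * spec$cell_size,
    spec$origin_y + (cells[, 1] - 0.5) * spec$cell_size))
  obs_blocks <- unique(block_of(observations$x, observations$y))
  tp <- sum(obs_blocks %in% occ_blocks)
  fa <- length(obs_blocks) - tp
  tibble::tibble(year = year, tp = tp, fa = fa,
                 sensitivity = tp / (tp + fa))
}
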