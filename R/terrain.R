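#' Relative luminance of an RGB raster
#'
#' Converts a 3-band orthomosaic to relative luminance on `[0, 1]` using
#' the Rec. 709 channel weights `Y = 0.2126 R + 0.7152 G + 0.0722 B` on
#' `[0, 1]`-scaled channels. On gravelly Arctic terrain, bright pixels mark
#' gravel with sparse vegetation and dark pixels denser plant cover or
#' exposed soil, so luminance doubles as a fine-scale substrate proxy.
#'
#' @param rgb An `rgb_raster` (values in `[0, 1]` or `[0, 255]`).
#' @param weights Channel weights, summing to 1.
#' @return A numeric `spread_raster` of luminance values.
#' @export
relative_luminance <- function(rgb, weights = c(0.2126, 0.7152, 0.0722)) {
  stopifnot(inherits(rgb, "rgb_raster"), length(weights) == 3)
  v <- rgb$values
  if (max(v) > 1) v <- v / 255
  y <- weights[1] * v[, , 1] + weights[2] * v[, , 2] + weights[3] * v[, , 3]
  raster_layer(rgb$spec, y)
}

#' Sample a luminance raster at point locations
#'
#' Nearest-pixel lookup: each point is mapped to its containing pixel
#' (half-open cell convention) and the pixel value returned. Points outside
#' the raster yield `NA` and a warning; an error is raised if no point
#' falls inside.
#'
#' @param points Data frame with `x`, `y` (m).
#' @param lum A luminance `spread_raster`.
#' @return Numeric vector of per-point luminance values.
#' @export
sample_luminance <- function(points, lum) {
  cells <- points_to_cells(points, lum$spec)
  if (!any(cells$inside)) stop("all points fall outside the luminance raster")
  if (any(!cells$inside)) {
    warning(sum(!cells$inside), " point(s) outside the raster sampled as NA")
  }
  out <- rep(NA_real_, nrow(points))
  ok <- cells$inside
  out[ok] <- lum$values[cbind(cells$row[ok], cells$col[ok])]
  out
}

#' Rigidly shift a point pattern
#'
#' Translates every point by the same `(dx, dy)`, preserving all pairwise
#' distances — the null-model move of the randomisation test. Admissibility
#' (no point leaving the raster extent) is the caller's concern.
#'
#' @param points Data frame with `x`, `y`.
#' @param dx,dy Shift components (m).
#' @return The shifted points.
#' @export
joint_shift <- function(points, dx, dy) {
  dplyr::mutate(points, x = .data$x + dx, y = .data$y + dy)
}

raster_extent <- function(spec) {
  c(xmin = spec$origin_x, xmax = spec$origin_x + spec$n_cols * spec$cell_size,
    ymin = spec$origin_y, ymax = spec$origin_y + spec$n_rows * spec$cell_size)
}

#' Joint-shift randomisation test of terrain (luminance) preference
#'
#' Tests whether individuals sit on brighter terrain than expected by
#' chance while preserving the internal spatial structure of the point
#' pattern: every iteration translates *all* points rigidly by a shift
#' drawn uniformly (and independently per axis) from
#' `[-max_shift, +max_shift]`. Shifts that would push any point off the
#' raster are rejected and redrawn, which keeps the null uniform on the
#' admissible set. Iteration 0 is the observed pattern; the p-value is the
#' proportion of all `n` iterations (the observed one included, so
#' `p >= 1/n`) whose median sampled luminance is at least the observed
#' median.
#'
#' @param points Data frame with `x`, `y` (>= 10 points).
#' @param lum A luminance `spread_raster`.
#' @param n Total iterations including the observed (default 1000).
#' @param max_shift Maximum per-axis shift (m), default 10.
#' @param seed Integer RNG seed.
#' @return A `randomisation_result`: `observed_median`, `null_medians`
#'   (length `n - 1`), `n`, `p_value`, `seed`.
#' @export
randomisation_test <- function(points, lum, n = 1000, max_shift = 10,
                               seed = 1) {
  if (nrow(points) < 10) stop("need at least 10 points")
  ext <- raster_extent(lum$spec)
  lo_dx <- ext["xmin"] - min(points$x); hi_dx <- ext["xmax"] - max(points$x)
  lo_dy <- ext["ymin"] - min(points$y); hi_dy <- ext["ymax"] - max(points$y)
  if (max(lo_dx, -max_shift) > min(hi_dx, max_shift) ||
      max(lo_dy, -max_shift) > min(hi_dy, max_shift)) {
    stop("no admissible joint shift keeps all points on the raster")
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  draw_admissible <- function(k, lo, hi) {
    out <- numeric(k); need <- seq_len(k); tries <- 0
    while (length(need) > 0) {
      cand <- stats::runif(length(need), -max_shift, max_shift)
      ok <- cand >= lo & cand <= hi
      out[need[ok]] <- cand[ok]
      need <- need[!ok]
      tries <- tries + 1
      if (tries > 1e4) stop("no admissible shift found after 1e4 draws")
    }
    out
  }
  dx <- draw_admissible(n - 1, lo_dx, hi_dx)
  dy <- draw_admissible(n - 1, lo_dy, hi_dy)
  spec <- lum$spec
  col0 <- floor((rep(points$x, n - 1) + rep(dx, each = nrow(points)) -
                   spec$origin_x) / spec$cell_size) + 1
  row0 <- floor((rep(points$y, n - 1) + rep(dy, each = nrow(points)) -
                   spec$origin_y) / spec$cell_size) + 1
  col0 <- pmin(pmax(col0, 1), spec$n_cols)
  row0 <- pmin(pmax(row0, 1), spec$n_rows)
  vals <- matrix(lum$values[cbind(row0, col0)], nrow = nrow(points))
  null_medians <- apply(vals, 2, stats::median)
  observed <- stats::median(sample_luminance(points, lum))
  p <- (1 + sum(null_medians >= observed)) / n
  structure(list(observed_median = observed, null_medians = null_medians,
                 n = n, p_value = p, max_shift = max_shift, seed = seed),
            class = "randomisation_result")
}

#' @export
print.randomisation_result <- function(x, ...) {
  cat(sprintf(
    "<randomisation_result> observed median %.4f vs null median %.4f (n = %d), p = %.4g\n",
    x$observed_median, stats::median(x$null_medians), x$n, x$p_value))
  invisible(x)
}
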