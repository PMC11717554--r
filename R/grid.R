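#' Grid specification for a planar raster
#'
#' Defines a regular square-celled grid in a projected planar coordinate
#' system (metres, north-up). The origin is the lower-left corner of the
#' grid; the centre of cell (row 1, col 1) sits at `origin + cell_size / 2`
#' on each axis. Rows increase northward, columns eastward. Cell extents are
#' half-open: a point lying exactly on a cell boundary belongs to the
#' higher-index cell.
#'
#' @param origin_x,origin_y Coordinates of the lower-left grid corner (m).
#' @param cell_size Side length of the square cells (m). Default 5, the
#'   resolution at which the spread simulations operate.
#' @param n_rows,n_cols Positive integer grid dimensions.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(origin_x = 0, origin_y = 0, cell_size = 5,
                      n_rows, n_cols) {
  stopifnot(is.numeric(cell_size), length(cell_size) == 1, cell_size > 0,
            n_rows >= 1, n_cols >= 1,
            is.finite(origin_x), is.finite(origin_y))
  structure(
    list(origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         cell_size = as.numeric(cell_size),
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g m, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y))
  invisible(x)
}

#' @export
format.grid_spec <- function(x, ...) {
  sprintf("%dx%d @ %gm", x$n_rows, x$n_cols, x$cell_size)
}

same_spec <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$cell_size - b$cell_size) < tol &&
    abs(a$origin_x - b$origin_x) < tol &&
    abs(a$origin_y - b$origin_y) < tol
}

# Cell-centre coordinate vectors (length n_cols / n_rows)
cell_centres_x <- function(spec) spec$origin_x + (seq_len(spec$n_cols) - 0.5) * spec$cell_size
cell_centres_y <- function(spec) spec$origin_y + (seq_len(spec$n_rows) - 0.5) * spec$cell_size

#' A raster on a grid_spec
#'
#' A thin matrix container: `values` is an `n_rows x n_cols` numeric or
#' logical matrix, row 1 being the southernmost row (row index increases with
#' northing). Missing data is represented as `NA` in memory; the `nodata`
#' sentinel only matters when reading and writing files.
#'
#' @param spec A [grid_spec()].
#' @param values Matrix of dimension `n_rows x n_cols`, or a scalar that is
#'   recycled.
#' @param nodata Sentinel value used on disk for missing cells.
#' @return A `spread_raster` object.
#' @export
raster_layer <- function(spec, values, nodata = -9999) {
  stopifnot(inherits(spec, "grid_spec"))
  if (length(values) == 1) {
    values <- matrix(values, spec$n_rows, spec$n_cols)
  }
  stopifnot(is.matrix(values),
            nrow(values) == spec$n_rows, ncol(values) == spec$n_cols)
  if (is.logical(values) && anyNA(values)) {
    stop("boolean rasters must not contain missing cells")
  }
  structure(list(spec = spec, values = values, nodata = nodata),
            class = "spread_raster")
}

#' @export
print.spread_raster <- function(x, ...) {
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  cat(sprintf("<spread_raster> %s, %s, range [%g, %g], %d NA\n",
              format(x$spec),
              if (is.logical(x$values)) "logical" else "numeric",
              rng[1], rng[2], sum(is.na(x$values))))
  invisible(x)
}

#' Convert a raster to a tidy tibble of cell centres
#'
#' @param x A `spread_raster`.
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `x`, `y`, `value`.
#' @method as_tibble spread_raster
#' @export
as_tibble.spread_raster <- function(x, ...) {
  spec <- x$spec
  tibble::tibble(
    row = rep(seq_len(spec$n_rows), times = spec$n_cols),
    col = rep(seq_len(spec$n_cols), each = spec$n_rows),
    x = rep(cell_centres_x(spec), each = spec$n_rows),
    y = rep(cell_centres_y(spec), times = spec$n_cols),
    value = as.vector(x$values))
}

#' Map points to grid cells
#'
#' Applies the half-open cell convention: `cell = floor((coord - origin) /
#' cell_size) + 1`, so a point exactly on a boundary is assigned to the
#' higher-index cell. Points outside the grid are flagged, never dropped.
#'
#' @param points A data frame with numeric `x` and `y` columns (m).
#' @param spec A [grid_spec()].
#' @return A tibble with columns `row`, `col` (integer, `NA` when outside)
#'   and `inside` (logical).
#' @export
points_to_cells <- function(points, spec) {
  stopifnot(inherits(spec, "grid_spec"), all(c("x", "y") %in% names(points)))
  col <- floor((points$x - spec$origin_x) / spec$cell_size) + 1
  row <- floor((points$y - spec$origin_y) / spec$cell_size) + 1
  inside <- row >= 1 & row <= spec$n_rows & col >= 1 & col <= spec$n_cols
  tibble::tibble(
    row = ifelse(inside, as.integer(row), NA_integer_),
    col = ifelse(inside, as.integer(col), NA_integer_),
    inside = inside)
}

#' Euclidean distance field from a point
#'
#' Each cell holds the distance (m) from its centre to `point`, e.g. the
#' station that acted as the introduction site.
#'
#' @param spec A [grid_spec()].
#' @param point Numeric length-2 vector `c(x, y)` or a one-row data frame
#'   with `x`, `y`.
#' @return A numeric `spread_raster`.
#' @export
distance_to_point <- function(spec, point) {
  pt <- as_xy(point)
  stopifnot(all(is.finite(pt)))
  dx <- cell_centres_x(spec) - pt[1]
  dy <- cell_centres_y(spec) - pt[2]
  vals <- sqrt(outer(dy^2, dx^2, `+`))
  raster_layer(spec, vals)
}

as_xy <- function(point) {
  if (is.data.frame(point)) {
    stopifnot(nrow(point) == 1, all(c("x", "y") %in% names(point)))
    return(c(point$x, point$y))
  }
  stopifnot(is.numeric(point), length(point) == 2)
  as.numeric(point)
}

# Minimum distance from points (px, py) to one polyline given as a
# two-column vertex matrix. Vectorised point-to-segment projection.
segment_min_dist <- function(px, py, verts) {
  stopifnot(ncol(verts) == 2, nrow(verts) >= 2)
  best <- rep(Inf, length(px))
  for (i in seq_len(nrow(verts) - 1)) {
    ax <- verts[i, 1]; ay <- verts[i, 2]
    bx <- verts[i + 1, 1]; by <- verts[i + 1, 2]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx^2 + vy^2
    if (len2 == 0) {
      d2 <- (px - ax)^2 + (py - ay)^2
    } else {
      t <- pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / len2))
      d2 <- (px - (ax + t * vx))^2 + (py - (ay + t * vy))^2
    }
    best <- pmin(best, d2)
  }
  sqrt(best)
}

trails_as_list <- function(trails) {
  if (is.matrix(trails)) return(list(trail = trails))
  if (is.data.frame(trails)) {
    stopifnot(all(c("x", "y") %in% names(trails)))
    key <- if ("trail" %in% names(trails)) trails$trail else "trail"
    return(lapply(split(trails[c("x", "y")], key), as.matrix))
  }
  if (is.list(trails)) return(lapply(trails, function(t) {
    if (is.data.frame(t)) as.matrix(t[c("x", "y")]) else as.matrix(t)
  }))
  stop("trails must be a tibble with columns trail/x/y, a matrix, or a list of matrices")
}

#' Euclidean distance field from a set of trails
#'
#' Per-cell minimum distance (m) from the cell centre to any segment of any
#' trail polyline.
#'
#' @param spec A [grid_spec()].
#' @param trails A tibble with columns `trail`, `x`, `y` (ordered vertices
#'   per trail), a two-column vertex matrix, or a list of such matrices.
#' @return A numeric `spread_raster`.
#' @export
distance_to_trails <- function(spec, trails) {
  tl <- trails_as_list(trails)
  if (length(tl) == 0) stop("at least one trail polyline is required")
  for (t in tl) if (nrow(t) < 2) stop("each trail needs at least 2 vertices")
  xs <- cell_centres_x(spec)
  ys <- cell_centres_y(spec)
  px <- rep(xs, each = spec$n_rows)
  py <- rep(ys, times = spec$n_cols)
  best <- rep(Inf, length(px))
  for (t in tl) best <- pmin(best, segment_min_dist(px, py, t))
  raster_layer(spec, matrix(best, spec$n_rows, spec$n_cols))
}

#' Rasterize a trail to a boolean on-trail mask
#'
#' A cell is on-trail iff its centre lies within `width / 2` of the
#' polyline. The default width of 2 m is the physical trail (and trail-plot)
#' width; on a 5-m grid a narrow trail passing between cell centres can
#' yield an empty mask, which is the documented behaviour of the
#' centre-membership rule.
#'
#' @param spec A [grid_spec()].
#' @param trail One polyline (two-column vertex matrix or tibble with
#'   `x`, `y`), or several in any form accepted by [distance_to_trails()].
#' @param width Full trail width (m), > 0.
#' @return A logical `spread_raster`.
#' @export
rasterize_trail <- function(spec, trail, width = 2) {
  stopifnot(width > 0)
  d <- distance_to_trails(spec, trail)
  raster_layer(spec, d$values <= width / 2)
}
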