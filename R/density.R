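#' Gaussian kernel density surface of occurrence records
#'
#' Evaluates a 2-D Gaussian kernel density estimate at every cell centre and
#' min-max normalises the surface to `[0, 1]` (a bounded "normalised KDE"
#' response for the density GLM, not an integral-normalised density). The
#' default bandwidth is Scott's rule on the point scatter: the bandwidth
#' matrix is the sample covariance scaled by `n^(-1/3)` (i.e.
#' `n^(-2/(d+4))` with `d = 2`), the standard multivariate-KDE choice. A
#' scalar bandwidth (in metres, isotropic) can be supplied instead and is
#' required when the points are degenerate.
#'
#' @param points Occurrence tibble (columns `x`, `y`; optional `abundance`
#'   used as weights when `weight_mode = "abundance"`).
#' @param spec A [grid_spec()] giving the evaluation grid.
#' @param bandwidth `"scott"` or a positive scalar (m).
#' @param weight_mode `"occurrence"` (each record counts once) or
#'   `"abundance"` (records weighted by individual counts).
#' @return A `density_surface`: list with `raster` (normalised values),
#'   `bandwidth` (2x2 matrix), `n_points`.
#' @export
kde_density <- function(points, spec, bandwidth = "scott",
                        weight_mode = c("occurrence", "abundance")) {
  weight_mode <- match.arg(weight_mode)
  n <- nrow(points)
  if (n < 1) stop("no points")
  w <- if (weight_mode == "abundance") points$abundance else rep(1, n)
  w <- w / sum(w)
  if (identical(bandwidth, "scott")) {
    if (n < 2) stop("Scott's rule needs >= 2 points; supply a scalar bandwidth")
    S <- stats::cov(cbind(points$x, points$y))
    H <- S * n^(-2 / 6)
    if (!all(is.finite(H)) || det(H) <= 0) {
      stop("singular Scott bandwidth (degenerate point scatter); ",
           "supply a scalar bandwidth")
    }
  } else {
    stopifnot(is.numeric(bandwidth), bandwidth > 0)
    H <- diag(bandwidth^2, 2)
  }
  Hinv <- solve(H)
  norm_const <- 1 / (2 * pi * sqrt(det(H)))
  xs <- cell_centres_x(spec)
  ys <- cell_centres_y(spec)
  vals <- matrix(0, spec$n_rows, spec$n_cols)
  # accumulate one Gaussian per point, vectorised over the grid
  for (i in seq_len(n)) {
    dx <- xs - points$x[i]          # length n_cols
    dy <- ys - points$y[i]          # length n_rows
    qx <- Hinv[1, 1] * dx^2
    qy <- Hinv[2, 2] * dy^2
    cross <- 2 * Hinv[1, 2] * outer(dy, dx)
    q <- outer(qy, qx, `+`) + cross
    vals <- vals + w[i] * norm_const * exp(-q / 2)
  }
  mx <- max(vals); mn <- min(vals)
  norm <- if (mx > mn) (vals - mn) / (mx - mn) else vals / mx
  structure(list(raster = raster_layer(spec, norm), bandwidth = H,
                 n_points = n, weight_mode = weight_mode),
            class = "density_surface")
}

#' @export
print.density_surface <- function(x, ...) {
  cat(sprintf("<density_surface> %s, n = %d points, bandwidth sd ~ (%.1f, %.1f) m\n",
              format(x$raster$spec), x$n_points,
              sqrt(x$bandwidth[1, 1]), sqrt(x$bandwidth[2, 2])))
  invisible(x)
}

#' Distance profile of occurrences from a reference point
#'
#' Histogram of (occurrence- or abundance-weighted) records by Euclidean
#' distance from a reference point (the station), normalised to a
#' probability distribution over the bins. Under a single introduction at
#' the reference, mass should peak near zero and decline with distance
#' (the abundant-centre expectation).
#'
#' @param points Occurrence tibble.
#' @param ref `c(x, y)` reference point (m).
#' @param bin_width Bin width (m), > 0.
#' @param weight_mode `"occurrence"` or `"abundance"`.
#' @return A tibble with `bin_lo`, `bin_hi`, `bin_mid`, `mass`
#'   (summing to 1).
#' @export
distance_profile <- function(points, ref, bin_width = 250,
                             weight_mode = c("occurrence", "abundance")) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(bin_width > 0)
  if (nrow(points) == 0) stop("no points")
  p <- as_xy(ref)
  d <- sqrt((points$x - p[1])^2 + (points$y - p[2])^2)
  w <- if (weight_mode == "abundance") points$abundance else rep(1, nrow(points))
  n_bins <- max(1, ceiling(max(d) / bin_width))
  if (max(d) == 0) n_bins <- 1
  bin <- pmin(floor(d / bin_width) + 1, n_bins)
  mass <- vapply(seq_len(n_bins), function(b) sum(w[bin == b]), numeric(1))
  tibble::tibble(
    bin_lo = (seq_len(n_bins) - 1) * bin_width,
    bin_hi = seq_len(n_bins) * bin_width,
    bin_mid = (seq_len(n_bins) - 0.5) * bin_width,
    mass = mass / sum(mass),
    weight_mode = weight_mode)
}

#' Classify occurrences by distance from the trails
#'
#' Assigns each record to a trail-distance class — on the trail and its
#' sides (0-100 m from the trail centre), the trailside region (0.1-1 km),
#' or farther away (> 1 km) by default — and summarises per-class record
#' counts and per-year median counts.
#'
#' @param points Occurrence tibble.
#' @param trails Trails in any form accepted by [distance_to_trails()].
#' @param class_edges Upper edges of the distance classes (m); the last
#'   class is open-ended.
#' @return A list with `points` (the input plus `dist_trail` and
#'   `class`), `counts` (per-class totals) and `yearly` (per class x year
#'   counts with per-class median across years).
#' @export
trail_distance_classes <- function(points, trails,
                                   class_edges = c(100, 1000)) {
  tl <- trails_as_list(trails)
  d <- rep(Inf, nrow(points))
  for (t in tl) d <- pmin(d, segment_min_dist(points$x, points$y, t))
  edges <- c(0, class_edges, Inf)
  labels <- c(sprintf("0-%gm", class_edges[1]),
              if (length(class_edges) > 1)
                sprintf("%g-%gm", class_edges[-length(class_edges)],
                        class_edges[-1]),
              sprintf(">%gm", class_edges[length(class_edges)]))
  cls <- cut(d, breaks = edges, labels = labels, right = TRUE,
             include.lowest = TRUE)
  pts <- dplyr::mutate(points, dist_trail = d, class = cls)
  counts <- dplyr::count(pts, .data$class, .drop = FALSE, name = "n")
  yearly <- dplyr::summarise(dplyr::group_by(pts, .data$class, .data$year),
                             n = dplyr::n(), .groups = "drop")
  medians <- dplyr::summarise(dplyr::group_by(yearly, .data$class),
                              median_per_year = stats::median(.data$n),
                              .groups = "drop")
  list(points = pts, counts = counts, yearly = yearly, medians = medians)
}

#' Paired rank test of on-trail vs off-trail abundance
#'
#' Wilcoxon signed-rank test on per-transect paired abundances (trail plot
#' vs its perpendicular off-trail plot). Zero differences are dropped; the
#' exact null distribution is used for n <= 25 pairs without ties, and the
#' normal approximation with tie correction otherwise. Two-sided.
#'
#' @param on_trail,off_trail Equal-length numeric vectors, one value per
#'   transect (n >= 5).
#' @return A one-row tibble with `statistic`, `p_value`, `n_pairs`,
#'   `n_used` (pairs remaining after dropping zero differences), `method`.
#' @export
paired_rank_test <- function(on_trail, off_trail) {
  stopifnot(length(on_trail) == length(off_trail))
  if (length(on_trail) < 5) stop("need at least 5 transect pairs")
  diffs <- on_trail - off_trail
  nz <- diffs[diffs != 0]
  if (length(nz) == 0) stop("all paired differences are zero; test undefined")
  exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  ht <- suppressWarnings(
    stats::wilcox.test(on_trail, off_trail, paired = TRUE, exact = exact,
                       correct = !exact))
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
                 n_pairs = length(on_trail), n_used = length(nz),
                 method = if (exact) "exact" else "normal approximation")
}

#' Share of surveyed individuals on the trail
#'
#' Percentage of all individuals (abundance-weighted records) whose record
#' lies on a trail plot — the headline contrast between trail and off-trail
#' establishment in a transect survey.
#'
#' @param survey Occurrence tibble with `plot_class` and `abundance`.
#' @return Percentage in `[0, 100]`.
#' @export
on_trail_share <- function(survey) {
  total <- sum(survey$abundance)
  if (total == 0) stop("empty survey")
  100 * sum(survey$abundance[survey$plot_class == "trail"]) / total
}
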