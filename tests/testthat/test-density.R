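test_that("KDE surface matches a brute-force Gaussian sum and normalises to 1", {
  set.seed(21)
  spec <- grid_spec(0, 0, 5, 40, 40)
  pts <- tibble::tibble(x = runif(30, 20, 180), y = runif(30, 20, 180))
  surf <- kde_density(pts, spec, bandwidth = "scott")
  expect_equal(max(surf$raster$values), 1)
  expect_true(all(surf$raster$values >= 0))

  # independent oracle: full-covariance Scott bandwidth, per-cell sum
  n <- nrow(pts)
  H <- stats::cov(cbind(pts$x, pts$y)) * n^(-1 / 3)
  Hi <- solve(H)
  raw <- matrix(0, 40, 40)
  for (r in 1:40) for (c in 1:40) {
    cx <- (c - 0.5) * 5; cy <- (r - 0.5) * 5
    s <- 0
    for (i in 1:n) {
      dv <- c(cx - pts$x[i], cy - pts$y[i])
      s <- s + exp(-0.5 * (t(dv) %*% Hi %*% dv)[1, 1])
    }
    raw[r, c] <- s / (n * 2 * pi * sqrt(det(H)))
  }
  oracle <- (raw - min(raw)) / (max(raw) - min(raw))
  expect_equal(surf$raster$values, oracle, tolerance = 1e-10)
})

test_that("KDE with a scalar bandwidth peaks at the point and is symmetric", {
  spec <- grid_spec(0, 0, 5, 21, 21)
  one <- tibble::tibble(x = 52.5, y = 52.5)   # centre of cell (11, 11)
  surf <- kde_density(one, spec, bandwidth = 10)
  expect_equal(which(surf$raster$values == 1, arr.ind = TRUE)[1, ],
               c(row = 11L, col = 11L))
  v <- surf$raster$values
  expect_equal(v, v[21:1, ], tolerance = 1e-12)      # N-S mirror
  expect_equal(v, t(v), tolerance = 1e-12)           # diagonal symmetry

  # two far-apart equal clusters give two equal maxima
  two <- tibble::tibble(x = c(20, 85), y = c(52.5, 52.5))
  s2 <- kde_density(two, spec, bandwidth = 6)$raster$values
  peaks <- sort(s2[s2 >= sort(s2, decreasing = TRUE)[2]], decreasing = TRUE)
  expect_equal(peaks[1], peaks[2], tolerance = 1e-9)

  expect_error(
    kde_density(tibble::tibble(x = c(1, 1), y = c(2, 2)), spec, "scott"),
    "singular|degenerate")
})

test_that("distance profiles are probability distributions with the right weights", {
  occ <- occurrences(c(7, 0), c(0, 0), 2023, c(3, 1),
                     c("trail", "trail"))
  # two records in different bins, abundance 3:1
  pr <- distance_profile(occ, ref = c(0, 0), bin_width = 5,
                         weight_mode = "abundance")
  expect_equal(sum(pr$mass), 1, tolerance = 1e-9)
  expect_equal(pr$mass, c(0.25, 0.75))

  # all points in one bin
  pr1 <- distance_profile(occ, ref = c(5, 0), bin_width = 100)
  expect_equal(pr1$mass, 1)
  expect_error(distance_profile(occ[0, ], c(0, 0), 5), "no points")

  # a station-seeded spread peaks near the station and decays
  sys <- small_system()
  sv <- sample_systematic_survey(sys$truth, sys$cfg$end_year, block = 100)
  pro <- distance_profile(sv, sys$landscape$station, bin_width = 100)
  expect_lte(which.max(pro$mass), ceiling(nrow(pro) / 2))
  expect_lt(mean(utils::tail(pro$mass, 3)), max(pro$mass))
})

test_that("trail-distance classes partition the records like a brute-force scan", {
  set.seed(31)
  trails <- tibble::tibble(trail = "t", x = c(0, 2000), y = c(0, 0))
  pts <- occurrences(x = runif(200, 0, 2000), y = runif(200, 0, 2500),
                     year = sample(c(1994, 2014, 2018), 200, TRUE))
  res <- trail_distance_classes(pts, trails)
  expect_equal(sum(res$counts$n), 200)
  oracle <- table(cut(pts$y, c(0, 100, 1000, Inf), include.lowest = TRUE))
  expect_equal(unname(res$counts$n), unname(as.integer(oracle)))

  on <- trail_distance_classes(occurrences(500, 0, 2018), trails)
  expect_equal(as.character(on$points$class), "0-100m")
})

test_that("paired rank test reproduces the exact enumeration null", {
  x <- c(1, 2, 3, 5, 4, 6)
  y <- c(2, 4, 6, 10, 8, 12)
  got <- paired_rank_test(x, y)
  # oracle: enumerate all 2^6 sign assignments of the rank sum
  d <- abs(y - x)
  rk <- rank(d)
  stat_obs <- sum(rk[(x - y) > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 6)))
  null_stats <- signs %*% rk
  p_oracle <- 2 * min(mean(null_stats <= stat_obs), mean(null_stats >= stat_obs))
  expect_equal(got$p_value, p_oracle)
  expect_equal(got$p_value, 0.03125)
  expect_equal(got$method, "exact")

  # swapping the vectors leaves the two-sided p unchanged
  expect_equal(paired_rank_test(y, x)$p_value, got$p_value)
  expect_error(paired_rank_test(x, x), "zero")
})

test_that("the density GLM recovers a noiseless linear response exactly", {
  ls <- make_landscape(synth_config(seed = 41, n_rows = 50, n_cols = 50))
  spec <- ls$spec
  z <- function(v) (v - mean(v)) / sd(v)
  d_st <- distance_to_point(spec, ls$station)$values
  resp <- raster_layer(spec, matrix(0.5 - 0.2 * z(as.vector(d_st)),
                                    spec$n_rows, spec$n_cols))
  m <- fit_density_glm(resp, ls$dem, ls$station, ls$trails,
                       family = "gaussian")
  expect_gt(m$r2[["r2"]], 0.999)
  est <- tidy(m)
  expect_equal(unname(est$estimate[est$term == "dist_station"]), -0.2,
               tolerance = 1e-6)
  others <- est$estimate[!est$term %in% c("(Intercept)", "dist_station")]
  expect_true(all(abs(others) < 1e-6))
})

test_that("GLM estimates are invariant to rescaling the map units", {
  ls <- make_landscape(synth_config(seed = 42, n_rows = 50, n_cols = 50))
  set.seed(42)
  resp_vals <- matrix(runif(50 * 50), 50, 50)
  m1 <- fit_density_glm(raster_layer(ls$spec, resp_vals), ls$dem,
                        ls$station, ls$trails)
  # same landscape expressed in kilometres
  spec_km <- grid_spec(0, 0, ls$spec$cell_size / 1000, 50, 50)
  dem_km <- raster_layer(spec_km, ls$dem$values)
  trails_km <- dplyr::mutate(ls$trails, x = x / 1000, y = y / 1000)
  m2 <- fit_density_glm(raster_layer(spec_km, resp_vals), dem_km,
                        ls$station / 1000, trails_km)
  expect_equal(tidy(m1)$estimate, tidy(m2)$estimate, tolerance = 1e-8)
})

test_that("partial R2 behaves as an identity for single-predictor models", {
  ls <- make_landscape(synth_config(seed = 43, n_rows = 50, n_cols = 50))
  spec <- ls$spec
  set.seed(43)
  d_st <- as.vector(distance_to_point(spec, ls$station)$values)
  z <- (d_st - mean(d_st)) / sd(d_st)
  resp <- raster_layer(spec, matrix(0.5 - 0.25 * z + rnorm(2500, 0, 0.1),
                                    spec$n_rows, spec$n_cols))
  m <- fit_density_glm(resp, ls$dem, ls$station, ls$trails,
                       interaction = FALSE)
  expect_true(all(m$partial_r2$partial_r2 >= 0 &
                    m$partial_r2$partial_r2 <= 1))

  # single-predictor model: the partial R2 equals the model R2
  df <- m$data
  single <- stats::glm(density ~ dist_station, data = df,
                       family = stats::gaussian())
  sse_f <- sum(residuals(single)^2)
  sse_0 <- sum((df$density - mean(df$density))^2)
  expect_equal((sse_0 - sse_f) / sse_0,
               1 - sse_f / sse_0, tolerance = 1e-12)
  m_single <- structure(list(fit = single, family = "gaussian"),
                        class = "density_glm")
  expect_equal(partial_r2(m_single)$partial_r2,
               model_r2_for_test(single), tolerance = 1e-10)
})

test_that("the poisson family path reports a McFadden-style R2 in range", {
  ls <- make_landscape(synth_config(seed = 44, n_rows = 50, n_cols = 50))
  set.seed(44)
  resp <- raster_layer(ls$spec, matrix(runif(2500), 50, 50))
  m <- suppressWarnings(
    fit_density_glm(resp, ls$dem, ls$station, ls$trails, family = "poisson"))
  expect_true(m$r2[["r2"]] >= 0 && m$r2[["r2"]] <= 1)
  expect_true(all(m$partial_r2$partial_r2 >= 0))
})
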