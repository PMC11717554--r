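test_that("elevation threshold is the highest observed elevation", {
  spec <- grid_spec(0, 0, 5, 10, 10)
  dem <- raster_layer(spec, matrix(seq(0, 148.5, by = 1.5), 10, 10))
  occ <- occurrences(c(2.5, 12.5, 47.5), c(2.5, 2.5, 47.5), 2018, 1)
  thr <- elevation_threshold(occ, dem)
  expect_equal(thr, max(dem$values[cbind(c(1, 1, 10), c(1, 3, 10))]))
  # duplicating records changes nothing
  expect_equal(elevation_threshold(rbind(occ, occ), dem), thr)
  far <- occurrences(1e6, 1e6, 2018, 1)
  expect_error(suppressWarnings(elevation_threshold(far, dem)), "no occurrence")
})

test_that("suitability is land below the threshold, cell by cell", {
  spec <- grid_spec(0, 0, 5, 12, 12)
  set.seed(71)
  dem <- raster_layer(spec, matrix(runif(144, 0, 160), 12, 12))
  water <- raster_layer(spec, matrix(runif(144) < 0.25, 12, 12))
  s <- build_suitability(dem, water, 137)
  for (i in c(1, 40, 77, 144)) {
    expect_equal(s$values[i], !water$values[i] && dem$values[i] <= 137)
  }
  all_water <- raster_layer(spec, matrix(TRUE, 12, 12))
  expect_false(any(build_suitability(dem, all_water, 137)$values))
  no_water <- raster_layer(spec, matrix(FALSE, 12, 12))
  expect_true(all(build_suitability(dem, no_water, Inf)$values))
  other <- raster_layer(grid_spec(0, 0, 10, 12, 12), matrix(FALSE, 12, 12))
  expect_error(build_suitability(dem, other, 137), "different grids")
})

test_that("kernel discretisation has the right radius, symmetry and mass", {
  f_exp <- kernel_fit("exponential", c(0, 2.26))
  k <- discretize_kernel(f_exp, cell_size = 5, truncation_q = 0.999)
  expect_equal(k$radius, ceiling(2.26 * log(1000) / 5))   # = 4
  w <- k$weights
  expect_equal(w, w[nrow(w):1, ])                 # dihedral symmetry
  expect_equal(w, t(w))
  expect_lte(sum(w), 1)
  expect_true(all(w >= 0))

  # truncation radius is monotone in the quantile
  r_lo <- discretize_kernel(f_exp, 5, truncation_q = 0.95)$radius
  expect_lte(r_lo, k$radius)

  # heavy tails are capped with a warning
  f_c <- kernel_fit("cauchy", c(22.2, 10))
  expect_warning(kc <- discretize_kernel(f_c, 5, 0.999, max_radius = 20L),
                 "capped")
  expect_equal(kc$radius, 20L)
})

test_that("FFT establishment probability equals direct convolution and kernel stamping", {
  set.seed(72)
  f_exp <- kernel_fit("exponential", c(0, 8))
  k <- discretize_kernel(f_exp, cell_size = 5, truncation_q = 0.99)
  spec <- grid_spec(0, 0, 5, 20, 20)

  empty <- raster_layer(spec, matrix(FALSE, 20, 20))
  expect_true(all(establishment_probability(empty, k)$values == 0))

  # impulse response: a single occupied cell stamps the kernel
  one <- matrix(FALSE, 20, 20); one[10, 11] <- TRUE
  p <- establishment_probability(raster_layer(spec, one), k)$values
  r <- k$radius
  expect_equal(p[(10 - r):(10 + r), (11 - r):(11 + r)], k$weights,
               tolerance = 1e-9)

  # random states match the nested-loop oracle
  for (i in 1:5) {
    st <- matrix(runif(400) < 0.3, 20, 20)
    direct <- trailspread:::direct_convolve(st * 1, k$weights)
    p2 <- establishment_probability(raster_layer(spec, st), k)$values
    expect_equal(p2, pmin(direct, 1), tolerance = 1e-9)
  }

  # the trail scenario combines the two sources as complement products
  trail <- raster_layer(spec, matrix(rep(c(TRUE, FALSE), c(5, 15)), 20, 20))
  st <- matrix(runif(400) < 0.2, 20, 20)
  k2 <- discretize_kernel(kernel_fit("exponential", c(0, 20)), 5, 0.99)
  got <- establishment_probability(raster_layer(spec, st), k, k2, trail,
                                   scenario = "trail_effect")$values
  p_l <- pmin(trailspread:::direct_convolve(st * 1, k$weights), 1)
  p_t <- pmin(trailspread:::direct_convolve((st & trail$values) * 1,
                                            k2$weights), 1)
  expect_equal(got, 1 - (1 - p_l) * (1 - p_t), tolerance = 1e-9)
})

test_that("yearly establishment follows Bernoulli(P_e) and never reverts", {
  n <- 100
  suit <- matrix(TRUE, n, n)
  state <- matrix(FALSE, n, n)
  set.seed(73)
  all_on <- step_year(state, matrix(1, n, n), suit)
  expect_true(all(all_on))
  unchanged <- step_year(state, matrix(0, n, n), suit)
  expect_false(any(unchanged))
  # occupied cells stay occupied even at P_e = 0
  expect_true(all(step_year(all_on, matrix(0, n, n), suit)))
  # unsuitable cells never flip
  expect_false(any(step_year(state, matrix(1, n, n), !suit)))
})

test_that("simulation histories are reproducible, monotone and suitability-bound", {
  sys <- small_system()
  fl <- kernel_fit("exponential", c(0, 8), assumption = "local")
  h1 <- run_simulation(sys$landscape, fl, scenario = "no_trail_effect",
                       start_year = 1928, end_year = 1948,
                       init_point = sys$landscape$station,
                       n_replicates = 2, base_seed = 5)
  h2 <- run_simulation(sys$landscape, fl, scenario = "no_trail_effect",
                       start_year = 1928, end_year = 1948,
                       init_point = sys$landscape$station,
                       n_replicates = 2, base_seed = 5)
  expect_identical(h1$arrival_year[[1]]$values, h2$arrival_year[[1]]$values)
  expect_identical(h1$arrival_year[[2]]$values, h2$arrival_year[[2]]$values)
  expect_false(identical(h1$arrival_year[[1]]$values,
                         h1$arrival_year[[2]]$values))

  suit <- build_suitability(sys$landscape$dem, sys$landscape$water_mask,
                            137)$values
  for (arr in h1$arrival_year) {
    expect_false(any(!is.na(arr$values) & !suit))
    expect_true(all(arr$values >= 1928 & arr$values <= 1948, na.rm = TRUE))
  }

  # a zero-length run occupies only the initial cell
  h0 <- run_simulation(sys$landscape, fl, scenario = "no_trail_effect",
                       start_year = 1928, end_year = 1928,
                       init_point = sys$landscape$station,
                       n_replicates = 1, base_seed = 1)
  expect_equal(sum(!is.na(h0$arrival_year[[1]]$values)), 1)
})

test_that("sensitivity counts covered observation blocks", {
  spec <- grid_spec(0, 0, 5, 60, 60)
  arr <- matrix(NA_real_, 60, 60)
  arr[1:40, 1:20] <- 1990   # south-west 100 x 200 m strip occupied
  h <- fake_history(spec, arr)
  obs <- occurrences(x = c(50, 50, 250), y = c(50, 150, 250),
                     year = 2014, abundance = 1, plot_class = "systematic_grid")
  res <- sensitivity(h, obs, year = 2014, eval_block = 100)
  expect_equal(res$tp, 2)
  expect_equal(res$fa, 1)
  expect_equal(res$sensitivity, 2 / 3)

  # full coverage and empty simulation bracket the score
  full <- fake_history(spec, matrix(1990, 60, 60))
  expect_equal(sensitivity(full, obs, 2014, 100)$sensitivity, 1)
  none <- fake_history(spec, matrix(NA_real_, 60, 60))
  expect_equal(sensitivity(none, obs, 2014, 100)$sensitivity, 0)
  expect_error(sensitivity(h, obs[0, ], 2014, 100), "no observations")
})
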