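test_that("ASCII grid rasters round-trip exactly, including nodata", {
  spec <- grid_spec(100, 200, 5, 3, 4)
  m <- matrix(as.numeric(1:12), 3, 4)
  m[2, 3] <- NA
  r <- raster_layer(spec, m)
  path <- withr::local_tempfile(fileext = ".asc")
  write_raster(r, path)
  back <- read_raster(path)
  expect_identical(back$spec, spec)
  expect_identical(back$values, m)
  expect_true(is.na(back$values[2, 3]))

  # all-zero grid parses with the right shape
  z <- raster_layer(grid_spec(0, 0, 5, 3, 3), matrix(0, 3, 3))
  pz <- withr::local_tempfile(fileext = ".asc")
  write_raster(z, pz)
  rz <- read_raster(pz)
  expect_equal(rz$spec$n_rows, 3)
  expect_true(all(rz$values == 0))
})

test_that("malformed ASCII grids are rejected with the offending part named", {
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 5", "NODATA_value -9999", "1 2", "3"), path)
  expect_error(read_raster(path), "expected 4")
  writeLines(c("ncols 2", "nrows 2", "xllcorner zero", "yllcorner 0",
               "cellsize 5", "NODATA_value -9999", "1 2", "3 4"), path)
  expect_error(read_raster(path), "xllcorner")
})

test_that("distance_to_point matches per-cell brute force and its geometry", {
  spec <- grid_spec(0, 0, 5, 10, 10)
  pt <- c(17.3, 42.1)
  d <- distance_to_point(spec, pt)
  oracle <- matrix(NA_real_, 10, 10)
  for (r in 1:10) for (c in 1:10) {
    oracle[r, c] <- sqrt(((c - 0.5) * 5 - pt[1])^2 + ((r - 0.5) * 5 - pt[2])^2)
  }
  expect_equal(d$values, oracle, tolerance = 1e-12)

  # a point at a cell centre has distance zero there
  expect_equal(distance_to_point(spec, c(12.5, 22.5))$values[5, 3], 0)
  # grid origin: cell (1,1) centre is at (2.5, 2.5)
  expect_equal(distance_to_point(spec, c(0, 0))$values[1, 1],
               sqrt(2.5^2 + 2.5^2))
})

test_that("distance_to_trails matches a brute-force segment oracle", {
  spec <- grid_spec(0, 0, 5, 15, 15)
  set.seed(1)
  trails <- dplyr::bind_rows(
    tibble::tibble(trail = "a", x = runif(4, 0, 75), y = runif(4, 0, 75)),
    tibble::tibble(trail = "b", x = runif(3, 0, 75), y = runif(3, 0, 75)))
  d <- distance_to_trails(spec, trails)
  for (probe in list(c(1, 1), c(8, 3), c(15, 15), c(4, 11))) {
    px <- (probe[2] - 0.5) * 5; py <- (probe[1] - 0.5) * 5
    best <- Inf
    for (nm in c("a", "b")) {
      v <- trails[trails$trail == nm, ]
      for (i in seq_len(nrow(v) - 1)) {
        best <- min(best, oracle_point_segment_dist(
          px, py, v$x[i], v$y[i], v$x[i + 1], v$y[i + 1]))
      }
    }
    expect_equal(d$values[probe[1], probe[2]], best, tolerance = 1e-12)
  }

  # perpendicular distance from a horizontal segment
  seg <- cbind(c(0, 75), c(12.5, 12.5))
  dh <- distance_to_trails(spec, seg)
  expect_equal(dh$values[5, 7], 10)   # cell centre 10 m north of the line
  expect_equal(dh$values[3, 7], 0)    # cell centre on the line
  expect_error(distance_to_trails(spec, list()), "at least one")
})

test_that("distance fields are non-negative and translation-equivariant", {
  spec <- grid_spec(0, 0, 5, 12, 12)
  shift <- c(1234.5, -987)
  spec2 <- grid_spec(shift[1], shift[2], 5, 12, 12)
  pt <- c(31, 27)
  expect_true(all(distance_to_point(spec, pt)$values >= 0))
  expect_equal(distance_to_point(spec, pt)$values,
               distance_to_point(spec2, pt + shift)$values)
  trail <- cbind(c(5, 50, 60), c(8, 30, 55))
  trail2 <- sweep(trail, 2, shift, `+`)
  expect_true(all(distance_to_trails(spec, trail)$values >= 0))
  expect_equal(distance_to_trails(spec, trail)$values,
               distance_to_trails(spec2, trail2)$values)
})

test_that("rasterize_trail equals thresholding the distance field and is monotone in width", {
  spec <- grid_spec(0, 0, 5, 15, 15)
  diag_trail <- cbind(c(0, 75), c(0, 75))
  for (w in c(2, 7, 20)) {
    mask <- rasterize_trail(spec, diag_trail, width = w)
    expect_identical(mask$values,
                     distance_to_trails(spec, diag_trail)$values <= w / 2)
  }
  narrow <- rasterize_trail(spec, diag_trail, width = 2)
  wide <- rasterize_trail(spec, diag_trail, width = 12)
  expect_true(all(wide$values[narrow$values]))

  # a trail along a row of cell centres with width 2 gives a 1-cell band
  row_trail <- cbind(c(0, 75), c(22.5, 22.5))
  band <- rasterize_trail(spec, row_trail, width = 2)
  expect_equal(unname(rowSums(band$values)), c(rep(0, 4), 15, rep(0, 10)))

  # a hairline trail between cell centres can select no cell at all
  off_trail <- cbind(c(0, 75), c(20, 20))
  expect_equal(sum(rasterize_trail(spec, off_trail, width = 0.1)$values), 0)
})

test_that("points_to_cells applies the half-open convention and round-trips", {
  spec <- grid_spec(0, 0, 5, 20, 20)
  expect_equal(points_to_cells(data.frame(x = 2.5, y = 2.5), spec)$row, 1L)
  expect_equal(points_to_cells(data.frame(x = 2.5, y = 2.5), spec)$col, 1L)
  # boundary points belong to the higher-index cell
  on_edge <- points_to_cells(data.frame(x = 5, y = 10), spec)
  expect_equal(unlist(on_edge[c("row", "col")]), c(row = 3L, col = 2L))
  # out-of-bounds flagged, not dropped
  out <- points_to_cells(data.frame(x = c(-1, 50), y = c(50, 101)), spec)
  expect_equal(out$inside, c(FALSE, FALSE))
  expect_equal(nrow(out), 2)

  set.seed(7)
  rows <- sample(20, 100, replace = TRUE)
  cols <- sample(20, 100, replace = TRUE)
  pts <- data.frame(x = (cols - 0.5) * 5, y = (rows - 0.5) * 5)
  got <- points_to_cells(pts, spec)
  expect_equal(got$row, rows)
  expect_equal(got$col, cols)
})

test_that("trails and station round-trip through GeoJSON, occurrences through CSV", {
  trails <- dplyr::bind_rows(
    tibble::tibble(trail = "south", x = c(0, 10, 20), y = c(50, 30, 10)),
    tibble::tibble(trail = "east", x = c(0, 40), y = c(50, 48)))
  gj <- withr::local_tempfile(fileext = ".geojson")
  write_trails_geojson(trails, gj, station = c(0, 50))
  back <- read_trails_geojson(gj)
  expect_equal(back$station, c(0, 50))
  expect_equal(dplyr::arrange(back$trails, trail, x),
               dplyr::arrange(trails, trail, x), tolerance = 1e-12)

  occ <- occurrences(c(1.5, 2), c(3, 4.25), 2023, c(1, 5),
                     c("trail", "off_trail"))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(occ, csv)
  expect_equal(as.data.frame(read_occurrences(csv)), as.data.frame(occ))
  expect_error(occurrences(1, 1, 2023, 0), "abundance")
  expect_error(occurrences(1, 1, 2023, 1, "roadside"), "plot_class")
})
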