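#' Read a raster from disk
#'
#' Supports ESRI ASCII grids (`.asc`), the plain-text interchange format used
#' for all shipped fixtures, and TIFF rasters accompanied by an ESRI world
#' file (`.tfw`) carrying the georeferencing. Only square cells are accepted.
#'
#' @param path Path to a `.asc` or `.tif`/`.tiff` file.
#' @param format `"auto"` (by extension), `"ascii_grid"` or `"tiff"`.
#' @return A `spread_raster`.
#' @export
read_raster <- function(path, format = c("auto", "ascii_grid", "tiff")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "ascii_grid"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         ascii_grid = read_ascii_grid(path),
         tiff = read_world_tiff(path))
}

#' Write a raster to disk
#'
#' @param x A `spread_raster`.
#' @param path Output path; format chosen as in [read_raster()].
#' @param format See [read_raster()].
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path, format = c("auto", "ascii_grid", "tiff")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "ascii_grid"
  }
  switch(format,
         ascii_grid = write_ascii_grid(x, path),
         tiff = write_world_tiff(x, path))
  invisible(path)
}

read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6) stop("ASCII grid too short: ", path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^\\s*[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2) stop("malformed ASCII grid header line: '", lines[i], "'")
    val <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(val)) stop("non-numeric value in header line: '", lines[i], "'")
    hdr[[tolower(parts[1])]] <- val
    i <- i + 1
  }
  for (key in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[key]])) stop("ASCII grid header missing '", key, "'")
  }
  if (!is.null(hdr$dx) && !is.null(hdr$dy) && hdr$dx != hdr$dy) {
    stop("non-square cells (dx != dy) are not supported")
  }
  # xllcenter variant: shift to corner convention
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner
         else if (!is.null(hdr$xllcenter)) hdr$xllcenter - hdr$cellsize / 2
         else stop("ASCII grid header missing 'xllcorner'")
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner
         else if (!is.null(hdr$yllcenter)) hdr$yllcenter - hdr$cellsize / 2
         else stop("ASCII grid header missing 'yllcorner'")
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  body <- paste(lines[i:length(lines)], collapse = " ")
  vals <- suppressWarnings(as.numeric(strsplit(trimws(body), "\\s+")[[1]]))
  if (anyNA(vals)) stop("non-numeric cell value in ASCII grid body of ", path)
  n_rows <- as.integer(hdr$nrows); n_cols <- as.integer(hdr$ncols)
  if (length(vals) != n_rows * n_cols) {
    stop(sprintf("ASCII grid body has %d values, expected %d (%d x %d)",
                 length(vals), n_rows * n_cols, n_rows, n_cols))
  }
  # file rows run north to south; internal rows run south to north
  m <- matrix(vals, n_rows, n_cols, byrow = TRUE)[n_rows:1, , drop = FALSE]
  m[m == nodata] <- NA
  raster_layer(grid_spec(xll, yll, hdr$cellsize, n_rows, n_cols), m,
               nodata = nodata)
}

write_ascii_grid <- function(x, path) {
  spec <- x$spec
  vals <- x$values
  if (is.logical(vals)) vals <- vals * 1L
  vals[is.na(vals)] <- x$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", spec$n_cols),
    sprintf("nrows %d", spec$n_rows),
    sprintf("xllcorner %.10g", spec$origin_x),
    sprintf("yllcorner %.10g", spec$origin_y),
    sprintf("cellsize %.10g", spec$cell_size),
    sprintf("NODATA_value %.10g", x$nodata)), con)
  flipped <- vals[spec$n_rows:1, , drop = FALSE]
  writeLines(apply(flipped, 1, function(r) paste(format(r, trim = TRUE, scientific = FALSE), collapse = " ")), con)
  invisible(path)
}

world_file_path <- function(path) sub("\\.tiff?$", ".tfw", path, ignore.case = TRUE)

read_world_tiff <- function(path) {
  tfw <- world_file_path(path)
  if (!file.exists(tfw)) stop("world file not found next to TIFF: ", tfw)
  w <- as.numeric(readLines(tfw, warn = FALSE))
  if (length(w) < 6 || anyNA(w)) stop("malformed world file: ", tfw)
  if (abs(w[1]) != abs(w[4]) || w[2] != 0 || w[3] != 0) {
    stop("world file implies rotated or non-square cells: ", tfw)
  }
  img <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(img)) == 3 && dim(img)[3] > 1) {
    stop("multi-band TIFF: use read_rgb_tiff() for orthomosaics")
  }
  m <- if (length(dim(img)) == 3) img[, , 1] else img
  cs <- w[1]
  n_rows <- nrow(m); n_cols <- ncol(m)
  # w[5], w[6]: centre of the upper-left pixel
  origin_x <- w[5] - cs / 2
  origin_y <- w[6] + cs / 2 - n_rows * cs
  raster_layer(grid_spec(origin_x, origin_y, cs, n_rows, n_cols),
               m[n_rows:1, , drop = FALSE])
}

write_world_tiff <- function(x, path, scale = NULL) {
  spec <- x$spec
  m <- x$values[spec$n_rows:1, , drop = FALSE]
  if (is.logical(m)) m <- m * 1
  m[is.na(m)] <- 0
  if (is.null(scale)) scale <- max(1, max(abs(m)))
  tiff::writeTIFF(m / scale, path, bits.per.sample = 32L)
  writeLines(format(c(spec$cell_size, 0, 0, -spec$cell_size,
                      spec$origin_x + spec$cell_size / 2,
                      spec$origin_y + spec$n_rows * spec$cell_size - spec$cell_size / 2),
                    scientific = FALSE),
             world_file_path(path))
  invisible(path)
}

#' Read occurrence records from CSV
#'
#' Expects the header `x,y,year,abundance,plot_class`. Abundance is the
#' number of individuals recorded within a 50-cm radius of the GPS point.
#'
#' @param path CSV path.
#' @return An occurrence tibble.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "year", "abundance", "plot_class")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("occurrence CSV missing columns: ", paste(miss, collapse = ", "))
  occurrences(df$x, df$y, df$year, df$abundance, df$plot_class)
}

#' Write occurrence records to CSV
#' @param occ Occurrence tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(occ, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct an occurrence record tibble
#'
#' @param x,y Coordinates (projected metres).
#' @param year Observation year.
#' @param abundance Individuals within the 50-cm recording radius (>= 1).
#' @param plot_class One of `"trail"`, `"off_trail"`, `"unsystematic"`,
#'   `"systematic_grid"`.
#' @return A tibble with one row per record.
#' @export
occurrences <- function(x, y, year, abundance = 1,
                        plot_class = "unsystematic") {
  out <- tibble::tibble(x = as.numeric(x), y = as.numeric(y),
                        year = as.integer(year),
                        abundance = as.integer(abundance),
                        plot_class = as.character(plot_class))
  if (any(out$abundance < 1)) stop("abundance must be >= 1")
  bad <- setdiff(unique(out$plot_class),
                 c("trail", "off_trail", "unsystematic", "systematic_grid"))
  if (length(bad)) stop("unknown plot_class: ", paste(bad, collapse = ", "))
  out
}

#' Read trails and station from GeoJSON
#'
#' Expects a FeatureCollection whose LineString features are trails (named
#' via a `name` property) and whose single Point feature, if present, is the
#' station. Coordinates are planar metres.
#'
#' @param path GeoJSON path.
#' @return A list with `trails` (tibble `trail`, `x`, `y`) and `station`
#'   (length-2 numeric or `NULL`).
#' @export
read_trails_geojson <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(g$features)) stop("not a GeoJSON FeatureCollection: ", path)
  trails <- list(); station <- NULL
  for (f in g$features) {
    geom <- f$geometry
    if (geom$type == "LineString") {
      nm <- if (!is.null(f$properties$name)) f$properties$name else paste0("trail", length(trails) + 1)
      coords <- do.call(rbind, lapply(geom$coordinates, unlist))
      trails[[nm]] <- tibble::tibble(trail = nm, x = coords[, 1], y = coords[, 2])
    } else if (geom$type == "Point") {
      station <- unlist(geom$coordinates)[1:2]
    }
  }
  list(trails = dplyr::bind_rows(trails), station = station)
}

#' Write trails and station to GeoJSON
#'
#' @param trails Tibble with `trail`, `x`, `y`.
#' @param path Output path.
#' @param station Optional `c(x, y)` station point.
#' @return `path`, invisibly.
#' @export
write_trails_geojson <- function(trails, path, station = NULL) {
  tl <- trails_as_list(trails)
  feats <- lapply(names(tl), function(nm) {
    list(type = "Feature", properties = list(name = nm),
         geometry = list(type = "LineString",
                         coordinates = unname(apply(tl[[nm]], 1, as.list))))
  })
  if (!is.null(station)) {
    feats <- c(feats, list(list(
      type = "Feature", properties = list(name = "station"),
      geometry = list(type = "Point", coordinates = as.list(as_xy(station))))))
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Construct a 3-band RGB raster
#'
#' @param spec A [grid_spec()].
#' @param values Array `n_rows x n_cols x 3` with channels in `[0, 1]`.
#' @return An `rgb_raster` object.
#' @export
rgb_raster <- function(spec, values) {
  stopifnot(inherits(spec, "grid_spec"), length(dim(values)) == 3,
            dim(values)[1] == spec$n_rows, dim(values)[2] == spec$n_cols,
            dim(values)[3] == 3)
  structure(list(spec = spec, values = values), class = "rgb_raster")
}

#' @export
print.rgb_raster <- function(x, ...) {
  cat(sprintf("<rgb_raster> %s, 3 bands in [%g, %g]\n", format(x$spec),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Read an RGB orthomosaic TIFF (with world file)
#' @param path TIFF path; a `.tfw` world file must sit next to it.
#' @return An `rgb_raster`.
#' @export
read_rgb_tiff <- function(path) {
  tfw <- world_file_path(path)
  if (!file.exists(tfw)) stop("world file not found next to TIFF: ", tfw)
  w <- as.numeric(readLines(tfw, warn = FALSE))
  img <- tiff::readTIFF(path)
  if (length(dim(img)) != 3 || dim(img)[3] < 3) stop("expected a 3-band TIFF: ", path)
  img <- img[, , 1:3, drop = FALSE]
  cs <- w[1]
  n_rows <- dim(img)[1]; n_cols <- dim(img)[2]
  spec <- grid_spec(w[5] - cs / 2, w[6] + cs / 2 - n_rows * cs, cs, n_rows, n_cols)
  rgb_raster(spec, img[n_rows:1, , , drop = FALSE])
}

#' Write an RGB orthomosaic TIFF (with world file)
#' @param x An `rgb_raster`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_rgb_tiff <- function(x, path) {
  spec <- x$spec
  tiff::writeTIFF(x$values[spec$n_rows:1, , , drop = FALSE], path,
                  bits.per.sample = 16L)
  writeLines(format(c(spec$cell_size, 0, 0, -spec$cell_size,
                      spec$origin_x + spec$cell_size / 2,
                      spec$origin_y + spec$n_rows * spec$cell_size - spec$cell_size / 2),
                    scientific = FALSE),
             world_file_path(path))
  invisible(path)
}
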