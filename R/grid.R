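#' Grid geometry for raster layers
#'
#' All raster layers in this package are plain numeric matrices on a shared
#' regular lat/lon grid, north-up (row 1 is the northernmost row). A
#' `grid_geometry` object records the cell-centre coordinates so that layers
#' can be located on the globe, plots can be snapped to pixels, and pixel
#' areas can be computed with the cosine-latitude correction.
#'
#' @param nrow,ncol Pixel counts.
#' @param lat_range,lon_range Numeric length-2, outer edges in degrees.
#' @return A `grid_geometry` list with cell-centre `lat` (decreasing) and
#'   `lon` (increasing) vectors and the cell sizes in degrees.
#' @export
grid_geometry <- function(nrow, ncol, lat_range, lon_range) {
  stopifnot(nrow >= 1, ncol >= 1, length(lat_range) == 2, length(lon_range) == 2)
  res_lat <- diff(sort(lat_range)) / nrow
  res_lon <- diff(sort(lon_range)) / ncol
  structure(list(
    nrow = as.integer(nrow), ncol = as.integer(ncol),
    lat = max(lat_range) - res_lat * (seq_len(nrow) - 0.5),
    lon = min(lon_range) + res_lon * (seq_len(ncol) - 0.5),
    res_lat = res_lat, res_lon = res_lon,
    lat_range = sort(lat_range), lon_range = sort(lon_range)
  ), class = "grid_geometry")
}

#' Per-pixel area in hectares
#'
#' Nominal cell area scaled by the cosine of the cell-centre latitude, the
#' standard equal-angle-grid correction. One degree is taken as 111.32 km.
#'
#' @param geom A [grid_geometry()].
#' @return Matrix of pixel areas (ha), same shape as the grid.
#' @export
pixel_area_ha <- function(geom) {
  km_per_deg <- 111.32
  cell_km2 <- (geom$res_lat * km_per_deg) * (geom$res_lon * km_per_deg)
  area_row <- cell_km2 * cos(geom$lat * pi / 180) * 100  # km^2 -> ha
  matrix(rep(area_row, geom$ncol), nrow = geom$nrow, ncol = geom$ncol)
}

#' Snap coordinates to grid cells
#'
#' @param geom A [grid_geometry()].
#' @param lat,lon Coordinate vectors (degrees).
#' @return Data frame with `row`, `col` (NA outside the grid extent).
#' @export
latlon_to_cell <- function(geom, lat, lon) {
  row <- ceiling((geom$lat_range[2] - lat) / geom$res_lat)
  col <- ceiling((lon - geom$lon_range[1]) / geom$res_lon)
  row[lat == geom$lat_range[2]] <- 1L
  col[lon == geom$lon_range[1]] <- 1L
  bad <- row < 1 | row > geom$nrow | col < 1 | col > geom$ncol
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Gaussian smoothing of a matrix
#'
#' Separable Gaussian convolution with reflected edges; this is the low-pass
#' filter that turns white noise into a spatially autocorrelated field.
#'
#' @param m Numeric matrix.
#' @param sigma Kernel standard deviation in pixels.
#' @return Smoothed matrix of the same shape.
#' @export
smooth_gaussian <- function(m, sigma) {
  stopifnot(is.matrix(m), sigma > 0)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(x) {
    # reflect-pad so the field keeps its variance near edges
    xp <- c(rev(x[seq_len(r)]), x, rev(x[length(x) - seq_len(r) + 1L]))
    out <- stats::filter(xp, k, sides = 2)
    as.numeric(out[(r + 1L):(r + length(x))])
  }
  m2 <- apply(m, 2L, conv1)
  t(apply(t(m2), 2L, conv1))
}

#' Spatially autocorrelated Gaussian random field
#'
#' Gaussian-filtered white noise, standardized to zero mean and unit
#' variance. Draws from the current RNG stream.
#'
#' @param nrow,ncol Grid size.
#' @param sigma Smoothing length scale in pixels.
#' @return Standardized matrix.
#' @export
gaussian_random_field <- function(nrow, ncol, sigma = 5) {
  f <- smooth_gaussian(matrix(stats::rnorm(nrow * ncol), nrow, ncol), sigma)
  (f - mean(f)) / stats::sd(f)
}

#' Empirical semivariogram of a gridded field
#'
#' Method-of-moments estimate on a random subset of pixel pairs, binned by
#' Euclidean pixel distance. Used to verify that generated fields carry
#' spatial autocorrelation (range of several pixels) rather than white noise.
#'
#' @param m Numeric matrix.
#' @param max_dist Largest pair distance (pixels) to consider.
#' @param n_pairs Number of random pixel pairs to sample.
#' @return Data frame with bin midpoint `dist` and `gamma` semivariance.
#' @export
empirical_variogram <- function(m, max_dist = 30, n_pairs = 20000) {
  nr <- nrow(m); nc <- ncol(m)
  i1 <- sample.int(nr, n_pairs, replace = TRUE)
  j1 <- sample.int(nc, n_pairs, replace = TRUE)
  i2 <- sample.int(nr, n_pairs, replace = TRUE)
  j2 <- sample.int(nc, n_pairs, replace = TRUE)
  d <- sqrt((i1 - i2)^2 + (j1 - j2)^2)
  keep <- d > 0 & d <= max_dist
  d <- d[keep]
  sq <- (m[cbind(i1, j1)][keep] - m[cbind(i2, j2)][keep])^2 / 2
  bin <- ceiling(d)
  data.frame(
    dist = sort(unique(bin)) - 0.5,
    gamma = as.numeric(tapply(sq, bin, mean))
  )
}

#' Practical autocorrelation range of a field
#'
#' First distance at which the empirical semivariance reaches 95% of its
#' sill (the mean semivariance over the last third of the bins).
#'
#' @inheritParams empirical_variogram
#' @return Range in pixels.
#' @export
variogram_range <- function(m, max_dist = 30, n_pairs = 20000) {
  v <- empirical_variogram(m, max_dist = max_dist, n_pairs = n_pairs)
  sill <- mean(v$gamma[v$dist > max_dist * 2 / 3])
  hit <- which(v$gamma >= 0.95 * sill)
  if (!length(hit)) return(max_dist)
  v$dist[hit[1]]
}
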