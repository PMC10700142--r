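#' Configuration of the synthetic world
#'
#' The synthetic world is a self-contained planet with a known potential
#' aboveground-carbon surface and a known degradation response, so that
#' every downstream stage of the pipeline (allometry, plot-to-pixel
#' scaling, counterfactual modelling, partitioning) can be validated
#' against ground truth. Human pressure `H` (an equal-weight mixture of
#' the eight human-disturbance layers) suppresses carbon through the
#' multiplier `(1 - H)^gamma_degradation`, and converts canopy to
#' urban/cropland/pasture land in proportion to the disturbance layers.
#'
#' @param grid_height,grid_width Pixel counts (>= 32).
#' @param lat_range,lon_range Outer grid edges in degrees.
#' @param n_env Number of environmental covariate layers.
#' @param gamma_degradation Non-negative exponent of the degradation
#'   response; 0 switches degradation off.
#' @param plot_density Inventory plots per 100 pixels.
#' @param smooth_sigma Gaussian length scale (pixels) of all random fields.
#' @param seed Integer seed; every random draw in the world derives from it.
#' @return A `world_config` list.
#' @export
world_config <- function(grid_height = 128, grid_width = 128,
                         lat_range = c(-32, 32), lon_range = c(-32, 32),
                         n_env = 40, gamma_degradation = 1,
                         plot_density = 5, smooth_sigma = 5, seed = 1) {
  if (grid_height < 32 || grid_width < 32)
    stop("grid dimensions must be at least 32x32")
  if (gamma_degradation < 0) stop("gamma_degradation must be >= 0")
  if (n_env < 4) stop("need at least 4 environmental layers")
  structure(list(
    grid_height = as.integer(grid_height), grid_width = as.integer(grid_width),
    lat_range = lat_range, lon_range = lon_range,
    n_env = as.integer(n_env), gamma_degradation = gamma_degradation,
    plot_density = plot_density, smooth_sigma = smooth_sigma,
    seed = as.integer(seed)
  ), class = "world_config")
}

#' Latitudinal biome bands
#'
#' Four bands by absolute latitude, poleward to equatorward:
#' boreal, temperate, dryland, tropical. Only biome-level constants
#' (allometry, carbon fraction, pool ratios) differ downstream, so the
#' band layout keeps the world reproducible without a biome model.
#'
#' @param geom A [grid_geometry()].
#' @return Character matrix with values in
#'   `c("tropical", "dryland", "temperate", "boreal")`.
#' @export
biome_bands <- function(geom) {
  amax <- max(abs(geom$lat_range))
  f <- abs(geom$lat) / amax
  lab <- ifelse(f < 0.25, "tropical",
         ifelse(f < 0.50, "dryland",
         ifelse(f < 0.75, "temperate", "boreal")))
  matrix(rep(lab, geom$ncol), geom$nrow, geom$ncol)
}

#' Generate the covariate stack of the synthetic world
#'
#' Produces `n_env` smooth environmental fields, eight human-disturbance
#' layers scaled to `[0, 1]` (0 = no human impact) built from a shared
#' spatial pressure base so they are mutually correlated, a binary
#' minimal-disturbance mask (all human layers < 1%), land-cover fractions
#' (urban, cropland, pasture, rangeland, water, ice) summing to <= 1 per
#' pixel, a root-mass-fraction layer with confidence bounds, and
#' soil-carbon-potential and absolute-error layers.
#'
#' @param config A [world_config()].
#' @return A `covariate_stack` list of matrices plus the grid geometry.
#' @export
generate_covariates <- function(config) {
  stopifnot(inherits(config, "world_config"))
  set.seed(config$seed)
  nr <- config$grid_height; nc <- config$grid_width
  sg <- config$smooth_sigma
  geom <- grid_geometry(nr, nc, config$lat_range, config$lon_range)

  env <- lapply(seq_len(config$n_env), function(i)
    gaussian_random_field(nr, nc, sg))
  names(env) <- sprintf("env_%02d", seq_len(config$n_env))

  # human layers: shared pressure base + layer-specific field, thresholded
  # so a substantial area has exactly zero human impact
  base <- gaussian_random_field(nr, nc, sg)
  human <- lapply(seq_len(8), function(j) {
    g <- 0.7 * base + 0.3 * gaussian_random_field(nr, nc, sg)
    pmin(pmax((g - 0.25) / 1.8, 0), 1)
  })
  names(human) <- c("urban_built", "managed_veg", "cropland_use",
                    "grazing_use", "pasture_use", "rangeland_use",
                    "modification", "accessibility")
  hmax <- Reduce(pmax, human)
  minimal <- hmax < 0.01

  H <- Reduce(`+`, human) / 8

  # land conversion follows the disturbance mixture; water and ice are
  # disturbance-independent background classes
  water <- ifelse(gaussian_random_field(nr, nc, sg) > 1.9, 0.8, 0)
  amax <- max(abs(geom$lat_range))
  ice <- matrix(rep(ifelse(abs(geom$lat) / amax > 0.97, 0.5, 0), nc), nr, nc)
  ice <- pmin(ice, pmax(0, 1 - water))
  room <- pmax(0, 1 - water - ice)
  conv <- pmin(0.9 * H, room)
  landcover <- list(
    urban = 0.05 * conv, cropland = 0.40 * conv,
    pasture = 0.30 * conv, rangeland = 0.25 * conv,
    water = water, ice = ice
  )

  rmf <- 0.15 + 0.20 * stats::plogis(gaussian_random_field(nr, nc, sg))
  rmf_lo <- rmf * 0.85
  rmf_hi <- pmin(rmf * 1.15, 0.59)

  soil_delta <- pmax(0, 25 * H + 4 * gaussian_random_field(nr, nc, sg))
  soil_error <- 0.25 * soil_delta + 0.5

  structure(list(
    geom = geom, env = env, human = human,
    minimal_disturbance = minimal, landcover = landcover,
    rmf = rmf, rmf_lo = rmf_lo, rmf_hi = rmf_hi,
    soil_delta = soil_delta, soil_error = soil_error,
    biome = biome_bands(geom)
  ), class = "covariate_stack")
}

#' Generate the ground truth of the synthetic world
#'
#' The potential aboveground carbon surface is a smooth positive function
#' of the environmental layers only (per-forest-area density times
#' potential canopy cover). Degradation multiplies carbon by
#' `(1 - H)^gamma` and removes canopy in proportion to the converted
#' land-cover fraction, so the world mixes density loss (degradation) and
#' cover loss (deforestation), which the partitioning stage must separate.
#'
#' @param stack A [generate_covariates()] stack.
#' @param config The matching [world_config()].
#' @return A `ground_truth` list of matrices: `potential_agc`,
#'   `degradation_multiplier`, `current_agc`, `potential_canopy`,
#'   `current_canopy`, `forest_density` plus `biome` and `geom`.
#' @export
generate_truth <- function(stack, config) {
  stopifnot(inherits(stack, "covariate_stack"))
  e <- stack$env
  biome_adj <- c(tropical = 0.8, temperate = 0, boreal = -0.6, dryland = -1.2)
  badj <- matrix(biome_adj[stack$biome], nrow(stack$biome), ncol(stack$biome))

  # per-forested-area density (t C / ha) and natural canopy, env-driven
  lc <- stack$landcover
  land <- pmax(0, 1 - lc$water - lc$ice)

  forest_density <- 30 + 220 *
    stats::plogis(0.9 * e[[1]] + 0.6 * e[[2]] - 0.4 * e[[3]] + badj)
  # water and ice area supports no trees even without humans
  potential_canopy <- 0.95 *
    stats::plogis(1.2 * e[[1]] + 0.5 * e[[4]] + 0.5 + badj) * land
  potential_agc <- forest_density * potential_canopy

  H <- Reduce(`+`, stack$human) / 8
  degradation_multiplier <- (1 - H)^config$gamma_degradation
  current_agc <- potential_agc * degradation_multiplier

  # canopy lost in proportion to the converted share of the land area
  conv <- lc$urban + lc$cropland + lc$pasture + lc$rangeland
  conv_land <- ifelse(land > 0, pmin(conv / land, 1), 0)
  current_canopy <- potential_canopy * (1 - conv_land)

  structure(list(
    potential_agc = potential_agc,
    degradation_multiplier = degradation_multiplier,
    current_agc = current_agc,
    potential_canopy = potential_canopy,
    current_canopy = current_canopy,
    forest_density = forest_density,
    human_index = H,
    biome = stack$biome, geom = stack$geom
  ), class = "ground_truth")
}

#' Reference allometric equations of the synthetic world
#'
#' The log-log diameter-biomass laws used to populate inventory plots.
#' These are the world's "true" allometries; the allometry module refits
#' them from pseudo-data downstream.
#'
#' @return Named list of [allometric_equation()] objects per biome.
#' @export
reference_allometries <- function() {
  list(
    tropical  = allometric_equation(-2.2, 2.45, biome = "tropical"),
    temperate = allometric_equation(-2.5, 2.40, biome = "temperate"),
    boreal    = allometric_equation(-2.7, 2.35, biome = "boreal"),
    dryland   = allometric_equation(-2.4, 2.30, biome = "dryland")
  )
}

#' Sample a forest inventory from the synthetic world
#'
#' Places plots preferentially (not exclusively) in pixels with canopy,
#' then fills each plot with trees whose diameters follow a truncated
#' Weibull (minimum 5 cm) until the plot's biomass under the world's
#' reference allometry matches the pixel's current carbon density times a
#' multiplicative lognormal error (mean 1). Plot canopy is taken to equal
#' the pixel's current canopy, so the plot carbon density targets the
#' pixel-scale carbon directly.
#'
#' @param truth A [generate_truth()] object.
#' @param config The matching [world_config()].
#' @param plot_area_m2 Plot area (default 250 m2).
#' @param noise_sdlog Lognormal plot-level noise on the log scale.
#' @return Data frame of tree records
#'   (`plot_id, lat, lon, year, area_m2, tree_id, dbh_cm, wood_density`),
#'   one row per tree; plots with zero trees appear with `tree_id = NA`.
#' @export
sample_inventory <- function(truth, config, plot_area_m2 = 250,
                             noise_sdlog = 0.15) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!any(truth$current_canopy >= 0.10))
    stop("no pixel has canopy cover >= 10%; world is unforested")
  set.seed(config$seed + 1L)
  geom <- truth$geom
  n_pix <- geom$nrow * geom$ncol
  n_plots <- max(1L, round(config$plot_density * n_pix / 100))

  prob <- as.numeric(truth$current_canopy) + 0.05
  cells <- sample.int(n_pix, n_plots, replace = TRUE, prob = prob)
  row <- ((cells - 1L) %% geom$nrow) + 1L
  col <- ((cells - 1L) %/% geom$nrow) + 1L

  eqs <- reference_allometries()
  cf <- default_carbon_fractions()
  dbh_shape <- 1.4; dbh_scale <- 12

  out <- vector("list", n_plots)
  for (p in seq_len(n_plots)) {
    i <- row[p]; j <- col[p]
    biome <- truth$biome[i, j]
    lat <- geom$lat[i] + stats::runif(1, -0.5, 0.5) * geom$res_lat
    lon <- geom$lon[j] + stats::runif(1, -0.5, 0.5) * geom$res_lon
    year <- sample(1995:2015, 1)
    noise <- stats::rlnorm(1, meanlog = -noise_sdlog^2 / 2, sdlog = noise_sdlog)
    target_density <- truth$current_agc[i, j] * noise     # t C / ha
    # total dry biomass the plot must carry (kg)
    target_kg <- target_density / cf[[biome]] * (plot_area_m2 / 1e4) * 1000
    dbh <- numeric(0)
    acc <- 0
    while (acc < target_kg && length(dbh) < 5000) {
      d <- 5 + stats::rweibull(1, shape = dbh_shape, scale = dbh_scale)
      dbh <- c(dbh, d)
      acc <- acc + predict_biomass(d, eqs[[biome]])
    }
    # the stopping rule overshoots by part of a tree; drop the last tree
    # when that leaves the plot closer to its target biomass
    if (length(dbh)) {
      w_last <- predict_biomass(dbh[length(dbh)], eqs[[biome]])
      if (abs(acc - w_last - target_kg) < abs(acc - target_kg))
        dbh <- dbh[-length(dbh)]
    }
    wd <- pmin(0.9, pmax(0.3, stats::rnorm(length(dbh), 0.55, 0.08)))
    out[[p]] <- if (length(dbh)) {
      data.frame(plot_id = p, lat = lat, lon = lon, year = year,
                 area_m2 = plot_area_m2, tree_id = seq_along(dbh),
                 dbh_cm = dbh, wood_density = wd)
    } else {
      data.frame(plot_id = p, lat = lat, lon = lon, year = year,
                 area_m2 = plot_area_m2, tree_id = NA_integer_,
                 dbh_cm = NA_real_, wood_density = NA_real_)
    }
  }
  do.call(rbind, out)
}

#' Build a complete synthetic world
#'
#' Convenience wrapper running [generate_covariates()], [generate_truth()]
#' and [sample_inventory()] from one configuration.
#'
#' @param config A [world_config()].
#' @return List with `config`, `stack`, `truth` and `trees`.
#' @export
synthesize_world <- function(config = world_config()) {
  stack <- generate_covariates(config)
  truth <- generate_truth(stack, config)
  trees <- sample_inventory(truth, config)
  list(config = config, stack = stack, truth = truth, trees = trees)
}
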