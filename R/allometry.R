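#' Log-log allometric equation
#'
#' The standard diameter-based biomass law `ln(W) = beta0 + beta1 * ln(DBH)`
#' with `W` in kg dry biomass and DBH in cm.
#'
#' @param beta0 Intercept on the ln-biomass scale.
#' @param beta1 Slope on ln-DBH; must be positive.
#' @param dbh_range Valid DBH interval (cm).
#' @param biome Optional biome label.
#' @param se Optional named numeric of standard errors.
#' @return An `allometric_equation` object.
#' @export
allometric_equation <- function(beta0, beta1, dbh_range = c(5, 300),
                                biome = NA_character_, se = NULL) {
  if (beta1 <= 0) stop("beta1 must be positive")
  structure(list(beta0 = beta0, beta1 = beta1,
                 dbh_range = dbh_range, biome = biome, se = se),
            class = "allometric_equation")
}

#' Predict tree dry biomass from diameter
#'
#' @param dbh DBH in cm, strictly positive.
#' @param eq An [allometric_equation()].
#' @return Dry biomass in kg.
#' @export
predict_biomass <- function(dbh, eq) {
  stopifnot(inherits(eq, "allometric_equation"))
  if (any(dbh <= 0)) stop("dbh must be positive")
  exp(eq$beta0 + eq$beta1 * log(dbh))
}

#' Pantropical wood-density power law
#'
#' Tropical biomass as `W = a * (rho * DBH^2)^b`, with configurable
#' coefficients. Trees without a wood-density value fall back to the
#' biome-median density (with a message).
#'
#' @param dbh DBH in cm, positive.
#' @param wood_density Wood density in g cm-3; `NA` triggers the fallback.
#' @param coeffs Named numeric `c(a = , b = )`.
#' @param fallback_density Biome-median wood density used for `NA` inputs.
#' @return Dry biomass in kg.
#' @export
predict_biomass_tropical <- function(dbh, wood_density,
                                     coeffs = c(a = 0.0673, b = 0.976),
                                     fallback_density = 0.6) {
  if (any(dbh <= 0)) stop("dbh must be positive")
  miss <- is.na(wood_density)
  if (any(miss)) {
    message(sum(miss), " tree(s) without wood density; using biome median ",
            fallback_density)
    wood_density[miss] <- fallback_density
  }
  if (any(wood_density < 0.2 | wood_density > 1.2))
    stop("wood density outside the plausible range [0.2, 1.2] g cm-3")
  coeffs[["a"]] * (wood_density * dbh^2)^coeffs[["b"]]
}

#' Back-calculated pseudo-data along the DBH gradient
#'
#' Evaluates an equation on the fixed diameter grid used to refit
#' biome-level allometries: every 1 cm from 5-25 cm, every 5 cm from
#' 25-100 cm, and every 10 cm from 100-300 cm, with shared endpoints
#' (25 and 100 cm) emitted once by the finer bin, giving 56 points.
#'
#' @param eq An [allometric_equation()].
#' @return Data frame with `dbh` and `biomass` columns.
#' @export
generate_pseudo_data <- function(eq) {
  grid <- c(seq(5, 25, by = 1), seq(30, 100, by = 5), seq(110, 300, by = 10))
  data.frame(dbh = grid, biomass = predict_biomass(grid, eq))
}

#' Fit a biome-level allometric equation from pooled pseudo-data
#'
#' Ordinary least squares of `ln(biomass)` on `ln(dbh)`.
#'
#' @param pseudo Data frame with `dbh` and `biomass` (pooled over the
#'   source equations of a biome).
#' @param biome Optional label carried into the result.
#' @return An [allometric_equation()] with `se` standard errors.
#' @export
fit_biome_equation <- function(pseudo, biome = NA_character_) {
  if (is.null(pseudo) || nrow(pseudo) == 0) stop("empty pseudo-data")
  if (length(unique(pseudo$dbh)) < 2)
    stop("degenerate design: need at least 2 distinct dbh values")
  fit <- stats::lm(log(biomass) ~ log(dbh), data = pseudo)
  cf <- stats::coef(fit)
  # pseudo-data can sit exactly on one line; the zero-residual warning from
  # summary.lm is expected there
  se <- suppressWarnings(stats::coef(summary(fit))[, "Std. Error"])
  allometric_equation(unname(cf[1]), unname(cf[2]),
                      dbh_range = range(pseudo$dbh), biome = biome,
                      se = c(beta0 = unname(se[1]), beta1 = unname(se[2])))
}

#' Biome-specific wood carbon fractions
#'
#' Proportion of dry biomass that is carbon. Defaults anchor the printed
#' biome endpoints (tropical moist broadleaf 45.6%, temperate conifer
#' 50.1%); other biomes use 47%.
#'
#' @return Named list of fractions.
#' @export
default_carbon_fractions <- function() {
  list(tropical = 0.456, temperate = 0.501, boreal = 0.47, dryland = 0.47)
}

#' Plot-level carbon density
#'
#' Sums tree biomass, converts to carbon with the biome carbon fraction,
#' and divides by the plot area:
#' `density (t C/ha) = sum(W_kg) / 1000 / (area_m2 / 1e4) * carbon_fraction`.
#' Plots measured in several years are averaged with equal weight per
#' calendar year.
#'
#' @param trees Data frame with `dbh_cm` (and optionally `year`); rows with
#'   `NA` dbh are treated as an empty (zero-tree) plot visit.
#' @param plot_area_m2 Plot area in m2, positive.
#' @param eq [allometric_equation()] used for every tree.
#' @param carbon_fraction Carbon fraction of dry biomass.
#' @return List with `carbon_density` (t C/ha), `n_trees` and `years`.
#' @export
plot_carbon_density <- function(trees, plot_area_m2, eq,
                                carbon_fraction = 0.47) {
  if (plot_area_m2 <= 0) stop("plot area must be positive")
  if (is.null(trees) || nrow(trees) == 0)
    return(list(carbon_density = 0, n_trees = 0L, years = integer(0)))
  if (is.null(trees$year)) trees$year <- 0L
  yr <- split(trees, trees$year)
  dens <- vapply(yr, function(tt) {
    dbh <- tt$dbh_cm[!is.na(tt$dbh_cm)]
    if (!length(dbh)) return(0)
    w_kg <- sum(predict_biomass(dbh, eq))
    w_kg / 1000 / (plot_area_m2 / 1e4) * carbon_fraction
  }, numeric(1))
  list(carbon_density = mean(dens),
       n_trees = sum(!is.na(trees$dbh_cm)),
       years = as.integer(names(yr)))
}

#' Median-absolute-deviation outlier mask
#'
#' Keeps values within `median +/- k * MAD`, where MAD is the raw median
#' absolute deviation (no normal-consistency constant). With
#' `transform = TRUE` the rule is applied on `log(x + 1)` to symmetrize
#' the skewed density distribution. When MAD is zero only values equal to
#' the median are kept.
#'
#' @param values Non-negative numeric vector.
#' @param k Window multiplier (default 2.5).
#' @param transform Apply the `log(x + 1)` transform first.
#' @return Logical keep mask.
#' @export
mad_filter <- function(values, k = 2.5, transform = TRUE) {
  stopifnot(k > 0, all(values >= 0, na.rm = TRUE))
  t <- if (transform) log(values + 1) else values
  med <- stats::median(t)
  mad0 <- stats::median(abs(t - med))
  abs(t - med) <= k * mad0
}

#' Apply the plot-level quality filters
#'
#' Removes (1) densities above the largest carbon density ever recorded
#' for forests (1,867 t C/ha) and (2) per-biome MAD outliers on the
#' `log(x + 1)` scale -- except that low-side outliers are kept in
#' human-modified non-forest landscapes (human-disturbance index > 10%
#' and canopy cover < 10%), so that trees outside forests are not
#' discarded. Plots sharing a pixel are averaged afterwards.
#'
#' @param plots Data frame with columns `plot_id`, `row`, `col`, `biome`,
#'   `carbon_density`, `human_index`, `canopy_pixel` (the last two sampled
#'   at the plot's pixel). Rows with `NA` `row`/`col` (outside the raster
#'   extent) are dropped with a warning.
#' @param k MAD window multiplier.
#' @param density_cap Absolute density cap in t C/ha.
#' @return Pixel-level data frame (`row`, `col`, `biome`, `carbon_density`,
#'   `human_index`, `canopy_pixel`, `n_plots`), filtered and averaged.
#' @export
apply_plot_filters <- function(plots, k = 2.5, density_cap = 1867) {
  outside <- is.na(plots$row) | is.na(plots$col)
  if (any(outside)) {
    warning(sum(outside), " plot(s) outside the raster extent; excluded")
    plots <- plots[!outside, , drop = FALSE]
  }
  plots <- plots[plots$carbon_density <= density_cap, , drop = FALSE]

  keep <- rep(TRUE, nrow(plots))
  for (b in unique(plots$biome)) {
    idx <- which(plots$biome == b)
    if (length(idx) < 3) next
    x <- plots$carbon_density[idx]
    inlier <- mad_filter(x, k = k, transform = TRUE)
    low_side <- log(x + 1) < stats::median(log(x + 1))
    exception <- plots$human_index[idx] > 0.10 & plots$canopy_pixel[idx] < 0.10
    keep[idx] <- inlier | (low_side & exception)
  }
  plots <- plots[keep, , drop = FALSE]

  agg <- stats::aggregate(
    cbind(carbon_density, human_index, canopy_pixel) ~ row + col + biome,
    data = plots, FUN = mean)
  n <- stats::aggregate(plot_id ~ row + col + biome, data = plots, FUN = length)
  agg$n_plots <- n$plot_id[match(paste(agg$row, agg$col),
                                 paste(n$row, n$col))]
  agg
}
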