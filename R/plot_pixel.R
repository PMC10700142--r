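#' Scale plot carbon to pixel carbon via canopy cover
#'
#' `C_pixel = C_plot / canopy_plot * canopy_pixel`: the plot density is
#' first expressed per unit of forested area by dividing by the canopy
#' cover assumed for the plot, then multiplied by the forested fraction of
#' the pixel. Under the "upper" convention the plot is assumed to sit at
#' the maximum canopy cover of the pixel (yielding the smaller carbon
#' value); under the "lower" convention at the mean canopy of the
#' forested (>= 10% cover) part (yielding the larger value).
#'
#' @param carbon_density Plot carbon density, t C/ha.
#' @param canopy_plot Canopy cover assumed inside the plot, in (0, 1].
#' @param canopy_pixel Canopy cover of the whole pixel, in \[0, 1\].
#' @return Pixel-scale carbon density, t C/ha.
#' @export
scale_plot_to_pixel <- function(carbon_density, canopy_plot, canopy_pixel) {
  stopifnot(all(canopy_pixel >= 0 & canopy_pixel <= 1))
  if (any(canopy_plot <= 0 & carbon_density > 0))
    stop("positive carbon with zero plot canopy is inconsistent")
  out <- ifelse(carbon_density == 0, 0,
                carbon_density / canopy_plot * canopy_pixel)
  out
}

#' Assemble the model training table
#'
#' Joins pixel-level carbon observations with the covariate stack:
#' environmental layers, human-disturbance layers, canopy cover and the
#' minimal-disturbance mask, plus pixel coordinates. Rows with any missing
#' covariate are dropped (count messaged). In the synthetic world no
#' sub-pixel canopy detail exists, so the upper and lower canopy
#' conventions coincide and a single `carbon` column is produced from
#' `canopy_plot = canopy_pixel`.
#'
#' @param pixels Data frame from [apply_plot_filters()] (`row`, `col`,
#'   `carbon_density`, `canopy_pixel`, ...).
#' @param stack A [generate_covariates()] stack.
#' @param current_canopy Matrix of current pixel canopy cover.
#' @return Data frame with `lat`, `lon`, `row`, `col`, `carbon`, `canopy`,
#'   `minimal`, and one column per covariate layer.
#' @export
build_training_table <- function(pixels, stack, current_canopy) {
  stopifnot(inherits(stack, "covariate_stack"))
  geom <- stack$geom
  inb <- pixels$row >= 1 & pixels$row <= geom$nrow &
         pixels$col >= 1 & pixels$col <= geom$ncol
  if (any(!inb)) {
    message(sum(!inb), " pixel observation(s) outside the stack extent; excluded")
    pixels <- pixels[inb, , drop = FALSE]
  }
  ij <- cbind(pixels$row, pixels$col)
  canopy_pixel <- current_canopy[ij]
  carbon <- scale_plot_to_pixel(pixels$carbon_density,
                                canopy_plot = pmax(pixels$canopy_pixel, 1e-6),
                                canopy_pixel = pmax(canopy_pixel, 1e-6))

  covs <- c(stack$env, stack$human)
  tab <- data.frame(
    lat = geom$lat[pixels$row], lon = geom$lon[pixels$col],
    row = pixels$row, col = pixels$col,
    carbon = carbon, canopy = canopy_pixel,
    minimal = stack$minimal_disturbance[ij]
  )
  for (nm in names(covs)) tab[[nm]] <- covs[[nm]][ij]
  cc <- stats::complete.cases(tab)
  if (any(!cc)) message(sum(!cc), " row(s) with missing covariates dropped")
  tab[cc, , drop = FALSE]
}

#' Full covariate table of every pixel in a stack
#'
#' Long-format table used for wall-to-wall prediction; one row per pixel
#' in column-major order with the same covariate columns as
#' [build_training_table()].
#'
#' @param stack A [generate_covariates()] stack.
#' @param canopy Matrix substituted as the `canopy` covariate (current
#'   canopy for current predictions, potential canopy for counterfactuals).
#' @param zero_human Set all eight human-disturbance covariates to zero
#'   (the type-1 counterfactual intervention).
#' @return Data frame with `row`, `col`, covariates and `canopy`.
#' @export
pixel_table <- function(stack, canopy, zero_human = FALSE) {
  geom <- stack$geom
  tab <- data.frame(
    row = rep(seq_len(geom$nrow), geom$ncol),
    col = rep(seq_len(geom$ncol), each = geom$nrow),
    canopy = as.numeric(canopy)
  )
  for (nm in names(stack$env)) tab[[nm]] <- as.numeric(stack$env[[nm]])
  for (nm in names(stack$human))
    tab[[nm]] <- if (zero_human) 0 else as.numeric(stack$human[[nm]])
  tab
}
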