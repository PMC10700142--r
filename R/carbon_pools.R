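#' Dead wood and litter to living-carbon ratios
#'
#' Forest-class ratios of dead wood plus litter carbon to living tree
#' carbon, with 95% confidence ranges: tropical 22% (15-33%), temperate
#' 33% (30-37%), boreal 80% (68-94%), dryland 21% (2-40%).
#'
#' @return Data frame with `class`, `mean`, `lo`, `hi` (fractions).
#' @export
default_pool_ratios <- function() {
  data.frame(
    class = c("tropical", "temperate", "boreal", "dryland"),
    mean = c(0.22, 0.33, 0.80, 0.21),
    lo   = c(0.15, 0.30, 0.68, 0.02),
    hi   = c(0.33, 0.37, 0.94, 0.40)
  )
}

#' Dead wood and litter carbon from living tree carbon
#'
#' Multiplies living tree carbon by the forest-class ratio; bounds
#' combine the ratio range with the living-carbon range by endpoint
#' products.
#'
#' @param living List with `mean`, `lo`, `hi` matrices of living carbon.
#' @param forest_class Character matrix of class labels.
#' @param ratios Data frame as [default_pool_ratios()].
#' @return List with `mean`, `lo`, `hi` matrices.
#' @export
dead_wood_litter <- function(living, forest_class, ratios = default_pool_ratios()) {
  classes <- unique(as.vector(forest_class))
  classes <- classes[!is.na(classes)]
  unknown <- setdiff(classes, ratios$class)
  if (length(unknown))
    stop("unknown forest class code(s): ", paste(unknown, collapse = ", "))
  idx <- match(as.vector(forest_class), ratios$class)
  shape <- function(v) matrix(v, nrow(forest_class), ncol(forest_class))
  r_mean <- shape(ratios$mean[idx])
  r_lo <- shape(ratios$lo[idx])
  r_hi <- shape(ratios$hi[idx])
  list(mean = living$mean * r_mean,
       lo = living$lo * r_lo,
       hi = living$hi * r_hi)
}

#' Soil carbon potential masked to naturally forested pixels
#'
#' Passes through the soil-carbon-potential layer for pixels that would
#' naturally support trees (potential canopy cover >= 10%); bounds are
#' the layer plus/minus its absolute-error layer (floored at 0).
#'
#' @param soil_delta Matrix of soil carbon potential, t C/ha.
#' @param soil_error Matrix of absolute errors (>= 0).
#' @param potential_canopy Matrix of potential canopy cover.
#' @return List with `mean`, `lo`, `hi` matrices (`NA` outside the mask).
#' @export
soil_potential <- function(soil_delta, soil_error, potential_canopy) {
  if (any(soil_error < 0, na.rm = TRUE)) stop("negative soil error layer")
  mask <- potential_canopy >= 0.10
  msk <- function(m) { m[!mask] <- NA; m }
  list(mean = msk(soil_delta),
       lo = msk(pmax(soil_delta - soil_error, 0)),
       hi = msk(soil_delta + soil_error))
}
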