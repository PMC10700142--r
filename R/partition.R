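#' Split the carbon deficit into conservation and restoration components
#'
#' Attributes the pixel deficit `c_pot - c_cur` to (a) lost canopy
#' (restoration potential) and (b) degradation of the standing forest
#' (conservation potential). The carbon expected from scaling current
#' carbon to the potential canopy, `baseline = c_cur * cc_pot / cc_cur`,
#' is attributed to canopy change; any excess `E = c_pot - baseline` is
#' distributed across the total potential canopy, i.e. in proportion
#' `cc_cur : (cc_pot - cc_cur)` to conservation : restoration. If the
#' potential falls short of the canopy-proportional baseline, the
#' shortfall is subtracted from the canopy-attributed restoration term
#' (floored at zero). Pixels with no deficit contribute zero to both
#' components and are flagged. The two components always sum exactly to
#' `max(c_pot - c_cur, 0)`.
#'
#' @param c_cur,c_pot Current and potential carbon (vectors or matrices),
#'   t C/ha, non-negative.
#' @param cc_cur,cc_pot Current and potential canopy cover fractions;
#'   `cc_cur > cc_pot` is clipped to `cc_pot` (with a message).
#' @return List with `conservation`, `restoration` (same shape as input)
#'   and logical `no_deficit` flag.
#' @export
partition_deficit <- function(c_cur, c_pot, cc_cur, cc_pot) {
  stopifnot(all(c_cur >= 0, na.rm = TRUE), all(c_pot >= 0, na.rm = TRUE))
  dm <- dim(c_cur)
  c_cur <- as.numeric(c_cur); c_pot <- as.numeric(c_pot)
  cc_cur <- as.numeric(cc_cur); cc_pot <- as.numeric(cc_pot)
  clip <- !is.na(cc_cur) & !is.na(cc_pot) & cc_cur > cc_pot
  if (any(clip)) {
    message(sum(clip), " pixel(s) with current canopy above potential; clipped")
    cc_cur[clip] <- cc_pot[clip]
  }
  n <- length(c_cur)
  cons <- rest <- numeric(n)
  no_deficit <- !is.na(c_pot) & !is.na(c_cur) & c_pot < c_cur
  deficit <- pmax(c_pot - c_cur, 0)

  same_cc <- cc_pot == cc_cur
  zero_cc <- cc_cur == 0 & !same_cc
  general <- !same_cc & !zero_cc & !no_deficit & !is.na(deficit)

  cons[same_cc & !no_deficit] <- deficit[same_cc & !no_deficit]
  rest[zero_cc & !no_deficit] <- deficit[zero_cc & !no_deficit]

  g <- which(general)
  if (length(g)) {
    baseline <- c_cur[g] * cc_pot[g] / cc_cur[g]
    canopy_term <- c_cur[g] * (cc_pot[g] / cc_cur[g] - 1)
    E <- pmax(c_pot[g] - baseline, 0)
    shortfall <- pmax(baseline - c_pot[g], 0)
    rest[g] <- pmax(canopy_term - shortfall, 0) +
      E * (cc_pot[g] - cc_cur[g]) / cc_pot[g]
    cons[g] <- E * cc_cur[g] / cc_pot[g]
  }
  na <- is.na(c_cur) | is.na(c_pot) | is.na(cc_cur) | is.na(cc_pot)
  cons[na] <- NA; rest[na] <- NA
  if (!is.null(dm)) {
    dim(cons) <- dm; dim(rest) <- dm; dim(no_deficit) <- dm
  }
  list(conservation = cons, restoration = rest, no_deficit = no_deficit)
}

#' Allocate the pixel deficit to land-cover classes
#'
#' Splits each pixel's deficit across the mapped land-cover classes
#' (urban, cropland, pasture, rangeland) in proportion to their pixel
#' fractions. The unattributed residual fraction (excluding water and
#' ice) goes to "low_human_pressure" in non-forest pixels (current canopy
#' < 10%) and to "forest" in forest pixels. Plantation deficit is tallied
#' separately (as a memo item, not an extra class) for pixels where
#' plantation cover exceeds 10% of the canopy area.
#'
#' @param deficit Matrix of the pixel deficit, t C/ha.
#' @param cover Named list of class-fraction matrices with elements
#'   `urban`, `cropland`, `pasture`, `rangeland`, `water`, `ice`.
#' @param canopy_cur Matrix of current canopy cover.
#' @param geom A [grid_geometry()] for stock totals.
#' @param plantation Optional matrix of plantation cover fraction.
#' @return Data frame with `land_use` and `deficit_gt` (Gt C), plus the
#'   attribute `plantation_gt`.
#' @export
allocate_land_cover <- function(deficit, cover, canopy_cur, geom,
                                plantation = NULL) {
  classes <- c("urban", "cropland", "pasture", "rangeland")
  fr_sum <- Reduce(`+`, cover)
  if (any(fr_sum > 1 + 1e-6, na.rm = TRUE))
    stop("land-cover fractions sum to more than 1")
  area <- pixel_area_ha(geom)
  gt <- function(m) sum(m * area, na.rm = TRUE) / 1e9

  alloc <- vapply(classes, function(cl) gt(deficit * cover[[cl]]), numeric(1))
  residual <- pmax(0, 1 - fr_sum)
  forest_px <- canopy_cur >= 0.10
  lhp <- gt(deficit * residual * !forest_px)
  forest <- gt(deficit * residual * forest_px)
  out <- data.frame(
    land_use = c(classes, "low_human_pressure", "forest"),
    deficit_gt = c(alloc, lhp, forest)
  )
  if (!is.null(plantation)) {
    pl_mask <- canopy_cur > 0 & plantation / pmax(canopy_cur, 1e-9) > 0.10
    attr(out, "plantation_gt") <- gt(deficit * residual * forest_px * pl_mask)
  }
  out
}

#' Six-source uncertainty budget
#'
#' Combines per-pixel absolute uncertainties from the six sources (model
#' type, input data, aboveground bootstrap, roots, dead wood and litter,
#' soil) by their linear sum, and reports relative shares plus the
#' dominant source per pixel. Ties break by the fixed source order.
#' A quadrature switch is available since uncorrelated errors are
#' conventionally combined in quadrature.
#'
#' @param sources Named list of six non-negative matrices/vectors, in the
#'   order `model_type`, `input_data`, `aboveground_bootstrap`, `roots`,
#'   `deadwood_litter`, `soil`.
#' @param combine `"sum"` (default) or `"quadrature"`.
#' @return List with `total`, `shares` (named list), `top_source`
#'   (character, `NA` where total is 0).
#' @export
uncertainty_budget <- function(sources, combine = c("sum", "quadrature")) {
  combine <- match.arg(combine)
  order_names <- c("model_type", "input_data", "aboveground_bootstrap",
                   "roots", "deadwood_litter", "soil")
  stopifnot(setequal(names(sources), order_names))
  sources <- sources[order_names]
  if (any(vapply(sources, function(s) any(s < 0, na.rm = TRUE), logical(1))))
    stop("uncertainty sources must be non-negative")
  dm <- dim(sources[[1]])
  mat <- sapply(sources, as.numeric)
  total <- if (combine == "sum") rowSums(mat) else sqrt(rowSums(mat^2))
  shares <- lapply(order_names, function(nm) {
    s <- if (combine == "sum") mat[, nm] / total else mat[, nm]^2 / total^2
    s[total == 0] <- NA
    if (!is.null(dm)) dim(s) <- dm
    s
  })
  names(shares) <- order_names
  top <- order_names[apply(mat, 1, which.max)]
  top[total == 0 | is.na(total)] <- NA_character_
  tt <- total
  if (!is.null(dm)) { dim(tt) <- dm; dim(top) <- dm }
  list(total = tt, shares = shares, top_source = top)
}
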