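#' Published per-model totals of potential living tree carbon
#'
#' The ten per-model totals (Gt C) reported by the published global
#' assessment that this package's accounting reproduces: four
#' ground-sourced models (type 1 and 2, upper and lower canopy
#' conventions) and six satellite-derived models (type 1 and 2 for each
#' of three input products). Bundled as worked-example input for
#' [ensemble_mean()] and [design_contrast()].
#'
#' @return Named numeric vector of Gt C totals.
#' @export
reference_model_totals <- function() {
  c(GS1_Upper = 487, GS1_Lower = 595,
    GS2_Upper = 517, GS2_Lower = 647,
    SD1_Harmonized = 552, SD1_ESACCI = 578, SD1_Walker = 669,
    SD2_Harmonized = 596, SD2_ESACCI = 645, SD2_Walker = 712)
}

#' Published carbon-deficit accounting table
#'
#' Mean differences between current and potential carbon stocks (Gt C)
#' by land-use type and carbon pool, with full model ranges, as printed
#' by the published global assessment, including its Sum row (which the
#' source rounds independently of the body rows). Bundled as
#' worked-example input for [budget_report()].
#'
#' @return Data frame with `land_use` and per-pool mean/lo/hi columns.
#' @export
reference_deficit_table <- function() {
  data.frame(
    land_use = c("urban", "cropland", "pasture", "rangeland",
                 "low_human_pressure", "forest", "sum"),
    living      = c(1.1, 38.3, 29.8, 24.6, 37.0, 84.7, 216.7),
    living_lo   = c(0.8, 25.5, 21.0, 11.4, 18.8, 68.7, 153.0),
    living_hi   = c(1.4, 50.7, 36.5, 38.7, 54.4, 105.0, 266.8),
    dead_litter    = c(0.3, 10.1, 7.6, 6.1, 12.2, 26.9, 61.8),
    dead_litter_lo = c(0.2, 6.7, 5.3, 2.8, 6.0, 25.9, 41.3),
    dead_litter_hi = c(0.4, 13.3, 9.2, 9.5, 17.2, 32.3, 76.2),
    soil    = c(0.3, 8.5, 6.0, 3.1, 4.2, 27.3, 49.3),
    soil_lo = c(0.2, 5.4, 3.5, 1.9, 2.4, 13.5, 26.8),
    soil_hi = c(0.5, 12.6, 9.4, 4.6, 10.5, 91.1, 128.7),
    total    = c(1.7, 56.8, 43.3, 33.7, 53.3, 138.9, 327.8),
    total_lo = c(1.2, 37.5, 29.8, 16.0, 27.2, 108.1, 221.1),
    total_hi = c(2.2, 76.6, 55.1, 52.9, 82.1, 228.4, 471.7)
  )
}

#' Ensemble mean of per-model carbon totals
#'
#' Arithmetic mean across ensemble member totals with the min-max model
#' range; the display value rounds to integer Gt.
#'
#' @param totals Named numeric vector of per-model totals (Gt C).
#' @return List with `mean_gt`, `range_gt` and `display_gt` (rounded).
#' @export
ensemble_mean <- function(totals) {
  if (!length(totals)) stop("no model totals supplied")
  list(mean_gt = mean(totals), range_gt = range(totals),
       display_gt = round(mean(totals)))
}

#' Classify model labels into type-1 and type-2 designs
#'
#' @param labels Character vector of model labels (`GS1_*`, `SD2_*`, ...).
#' @return Character vector `"type1"`/`"type2"`.
#' @export
design_type <- function(labels) {
  out <- rep(NA_character_, length(labels))
  out[grepl("^(GS|SD)1", labels)] <- "type1"
  out[grepl("^(GS|SD)2", labels)] <- "type2"
  if (anyNA(out))
    stop("unknown design label(s): ",
         paste(labels[is.na(out)], collapse = ", "))
  out
}

#' Contrast between two groups of model totals
#'
#' `mean(group_b) - mean(group_a)`, with a rounded display value; used
#' for the type-2 minus type-1 comparison.
#'
#' @param totals Named numeric vector of per-model totals (Gt C).
#' @param group_a,group_b Character vectors of labels; both must exist in
#'   `names(totals)`.
#' @return List with `diff_gt` and `display_gt`.
#' @export
design_contrast <- function(totals, group_a, group_b) {
  missing <- setdiff(c(group_a, group_b), names(totals))
  if (length(missing))
    stop("unknown design label(s): ", paste(missing, collapse = ", "))
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  d <- mean(totals[group_b]) - mean(totals[group_a])
  list(diff_gt = d, display_gt = round(d))
}

#' Summary report of a carbon-deficit budget
#'
#' Derives the headline accounting from a land-use by carbon-pool deficit
#' table: the total deficit, the deficit outside urban + cropland +
#' pasture, the conservation (existing forest) and restoration
#' (rangeland + low-human-pressure) components and their shares, the
#' converted-lands total with per-class shares, the urban + cropland +
#' pasture total, and the carbon-pool shares. Display values round Gt to
#' integers and shares to whole percent, computed from unrounded values.
#' If the table carries a `"sum"` row it is used for the pool and grand
#' totals (matching a source that rounds its Sum row independently);
#' otherwise totals are recomputed from the body rows.
#'
#' @param budget Data frame with `land_use` and at least `living`,
#'   `dead_litter`, `soil` columns (Gt C); an optional `total` column
#'   overrides the row-wise pool sum.
#' @return List of totals (Gt) and shares (%), with `display` holding the
#'   rounded headline values.
#' @export
budget_report <- function(budget) {
  required <- c("urban", "cropland", "pasture", "rangeland",
                "low_human_pressure", "forest")
  missing <- setdiff(required, budget$land_use)
  if (length(missing))
    stop("missing land-use row(s): ", paste(missing, collapse = ", "))
  sum_row <- budget[budget$land_use == "sum", , drop = FALSE]
  body <- budget[budget$land_use != "sum", , drop = FALSE]
  if (is.null(body$total))
    body$total <- body$living + body$dead_litter + body$soil

  row_total <- function(lu) body$total[body$land_use == lu]
  pools <- if (nrow(sum_row)) {
    c(living = sum_row$living, dead_litter = sum_row$dead_litter,
      soil = sum_row$soil)
  } else {
    c(living = sum(body$living), dead_litter = sum(body$dead_litter),
      soil = sum(body$soil))
  }
  total <- sum(pools)

  ucp <- sum(vapply(c("urban", "cropland", "pasture"), row_total, numeric(1)))
  conservation <- row_total("forest")
  restoration <- row_total("rangeland") + row_total("low_human_pressure")
  outside_ucp <- conservation + restoration
  converted <- sum(body$total) - conservation

  conv_classes <- c("urban", "cropland", "pasture", "rangeland",
                    "low_human_pressure")
  conv_shares <- vapply(conv_classes, function(lu)
    100 * row_total(lu) / converted, numeric(1))
  livestock_share <- conv_shares[["pasture"]] + conv_shares[["rangeland"]]
  pool_shares <- 100 * pools / total

  list(
    total_gt = total,
    outside_ucp_gt = outside_ucp,
    ucp_gt = ucp,
    conservation_gt = conservation,
    restoration_gt = restoration,
    converted_gt = converted,
    conservation_share_pct = 100 * conservation / outside_ucp,
    restoration_share_pct = 100 * restoration / outside_ucp,
    converted_shares_pct = conv_shares,
    livestock_share_pct = livestock_share,
    pool_shares_pct = pool_shares,
    display = list(
      total_gt = round(total, 1),
      outside_ucp_gt = round(outside_ucp),
      ucp_gt = round(ucp),
      conservation_gt = round(conservation),
      restoration_gt = round(restoration),
      converted_gt = round(converted),
      conservation_share_pct = round(100 * conservation / outside_ucp),
      restoration_share_pct = round(100 * restoration / outside_ucp),
      cropland_share_pct = round(conv_shares[["cropland"]]),
      livestock_share_pct = round(livestock_share)
    )
  )
}
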