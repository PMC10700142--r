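#' Plot-level carbon table from a tree inventory
#'
#' Refits biome-level allometric equations from back-calculated
#' pseudo-data of the supplied source equations, computes each plot's
#' carbon density (year-averaged), snaps plots to pixels and attaches the
#' pixel's biome, human-disturbance index and current canopy cover.
#'
#' @param trees Tree-record data frame as written by [sample_inventory()].
#' @param stack A [generate_covariates()] stack.
#' @param current_canopy Matrix of current canopy cover.
#' @param source_equations Named list of [allometric_equation()] per
#'   biome to back-calculate from; defaults to [reference_allometries()].
#' @param carbon_fractions Named list as [default_carbon_fractions()].
#' @return Data frame with one row per plot: `plot_id`, `row`, `col`,
#'   `biome`, `carbon_density`, `human_index`, `canopy_pixel`, `n_trees`.
#' @export
plot_carbon_table <- function(trees, stack, current_canopy,
                              source_equations = reference_allometries(),
                              carbon_fractions = default_carbon_fractions()) {
  geom <- stack$geom
  human_index <- Reduce(`+`, stack$human) / length(stack$human)
  fitted <- lapply(names(source_equations), function(b)
    fit_biome_equation(generate_pseudo_data(source_equations[[b]]), biome = b))
  names(fitted) <- names(source_equations)

  per_plot <- split(trees, trees$plot_id)
  out <- lapply(per_plot, function(tt) {
    cell <- latlon_to_cell(geom, tt$lat[1], tt$lon[1])
    if (is.na(cell$row))
      return(data.frame(plot_id = tt$plot_id[1], row = NA_integer_,
                        col = NA_integer_, biome = NA_character_,
                        carbon_density = NA_real_, human_index = NA_real_,
                        canopy_pixel = NA_real_, n_trees = 0L))
    biome <- stack$biome[cell$row, cell$col]
    pc <- plot_carbon_density(tt, tt$area_m2[1], fitted[[biome]],
                              carbon_fraction = carbon_fractions[[biome]])
    data.frame(plot_id = tt$plot_id[1], row = cell$row, col = cell$col,
               biome = biome, carbon_density = pc$carbon_density,
               human_index = human_index[cell$row, cell$col],
               canopy_pixel = current_canopy[cell$row, cell$col],
               n_trees = pc$n_trees)
  })
  do.call(rbind, out)
}

#' Run the full carbon-potential pipeline on a synthetic world
#'
#' End-to-end orchestration: world generation, allometric plot carbon,
#' quality filters, plot-to-pixel scaling, counterfactual ensemble
#' modelling per design, root/dead-wood/soil pool scaling, deficit
#' partitioning, land-cover allocation and the uncertainty budget.
#'
#' @param config A [world_config()].
#' @param designs Character subset of `c("GS1", "GS2", "SD1", "SD2")`.
#' @param n_bootstrap Ensemble size per design.
#' @param seed Seed for the model bootstrap (world draws use
#'   `config$seed`).
#' @param world Optionally a pre-built [synthesize_world()] result (the
#'   `config` argument is then ignored).
#' @return List with the world, the training table, per-design potential
#'   and current predictions and stock totals, the pixel deficit, its
#'   partition, the land-use budget table and the uncertainty budget.
#' @export
run_pipeline <- function(config = world_config(), designs = c("GS1", "GS2"),
                         n_bootstrap = 25, seed = 1, world = NULL) {
  if (is.null(world)) world <- synthesize_world(config)
  stack <- world$stack
  truth <- world$truth
  geom <- stack$geom

  plots <- plot_carbon_table(world$trees, stack, truth$current_canopy)
  pixels <- apply_plot_filters(plots)
  train <- build_training_table(pixels, stack, truth$current_canopy)

  pot_mask <- truth$potential_canopy >= 0.10
  fits <- list(); potential <- list(); current <- list(); totals <- c()
  for (d in designs) {
    spec <- model_spec(design = d, n_bootstrap = n_bootstrap, seed = seed)
    tab <- if (d %in% c("SD1", "SD2"))
      sd_training_table(truth$current_agc, stack, truth$current_canopy)
    else train
    ens <- fit_ensemble(tab, spec)
    pot <- predict_potential(ens, stack, truth$potential_canopy)
    cur <- predict_current(ens, stack, truth$current_canopy, mask = pot_mask)
    fits[[d]] <- ens
    potential[[d]] <- pot
    current[[d]] <- cur
    totals[d] <- total_stock(pot$mean, geom)
  }

  # pool scaling and deficit use the average across the fitted designs
  pot_mean <- Reduce(`+`, lapply(potential, `[[`, "mean")) / length(designs)
  cur_mean <- Reduce(`+`, lapply(current, `[[`, "mean")) / length(designs)

  living_pot <- add_root_carbon(pot_mean, stack$rmf,
                                agc_lo = Reduce(pmin, lapply(potential, `[[`, "q05")),
                                agc_hi = Reduce(pmax, lapply(potential, `[[`, "q95")),
                                rmf_lo = stack$rmf_lo, rmf_hi = stack$rmf_hi)
  living_cur <- add_root_carbon(cur_mean, stack$rmf,
                                rmf_lo = stack$rmf_lo, rmf_hi = stack$rmf_hi)

  deficit_living <- list(
    mean = pmax(living_pot$mean - living_cur$mean, 0),
    lo = pmax(living_pot$lo - living_cur$mean, 0),
    hi = pmax(living_pot$hi - living_cur$mean, 0)
  )
  dead <- dead_wood_litter(deficit_living, stack$biome)
  soil <- soil_potential(stack$soil_delta, stack$soil_error,
                         truth$potential_canopy)
  deficit_total <- deficit_living$mean + dead$mean +
    ifelse(is.na(soil$mean), 0, soil$mean)
  deficit_total[!pot_mask] <- NA

  part <- partition_deficit(living_cur$mean, living_pot$mean,
                            truth$current_canopy, truth$potential_canopy)

  budget <- data.frame(
    allocate_land_cover(deficit_living$mean, stack$landcover,
                        truth$current_canopy, geom)["land_use"],
    living = allocate_land_cover(deficit_living$mean, stack$landcover,
                                 truth$current_canopy, geom)$deficit_gt,
    dead_litter = allocate_land_cover(dead$mean, stack$landcover,
                                      truth$current_canopy, geom)$deficit_gt,
    soil = allocate_land_cover(ifelse(is.na(soil$mean), 0, soil$mean),
                               stack$landcover, truth$current_canopy,
                               geom)$deficit_gt
  )

  unc <- uncertainty_budget(list(
    model_type = if (length(designs) >= 2)
      Reduce(function(a, b) abs(a - b),
             lapply(potential[1:2], `[[`, "mean")) / 2
      else pot_mean * 0,
    input_data = pot_mean * 0,
    aboveground_bootstrap = (Reduce(pmax, lapply(potential, `[[`, "q95")) -
                             Reduce(pmin, lapply(potential, `[[`, "q05"))) / 2,
    roots = (living_pot$hi - living_pot$lo) / 2,
    deadwood_litter = (dead$hi - dead$lo) / 2,
    soil = ifelse(is.na(soil$mean), 0, stack$soil_error)
  ))

  list(world = world, plots = plots, train = train,
       ensembles = fits, potential = potential, current = current,
       potential_totals_gt = totals,
       deficit_living = deficit_living, deficit_total = deficit_total,
       partition = part, budget = budget, uncertainty = unc,
       pot_mask = pot_mask)
}

#' Recovery metrics of a pipeline run against ground truth
#'
#' Compares a design's ensemble-mean potential map with the known
#' potential surface of the synthetic world: R-squared to the 1:1 line,
#' relative mean bias, and the relative error of the estimated total
#' deficit (estimated potential minus estimated current stock versus the
#' true deficit), all over the natural-forest mask.
#'
#' @param result A [run_pipeline()] result.
#' @param design Which design's maps to score.
#' @return List with `r2`, `mean_bias`, `deficit_rel_error`,
#'   `true_deficit_gt`, `est_deficit_gt`.
#' @export
evaluate_recovery <- function(result, design = "GS1") {
  truth <- result$world$truth
  geom <- truth$geom
  mask <- result$pot_mask
  est <- result$potential[[design]]$mean
  obs <- truth$potential_agc
  ok <- mask & !is.na(est)
  r2 <- r2_one_to_one(obs[ok], est[ok])
  bias <- mean(est[ok]) / mean(obs[ok]) - 1

  # deficit as a stock difference (potential minus current total), the
  # same contrast the headline accounting reports
  est_cur <- result$current[[design]]$mean
  est_deficit <- total_stock(est, geom, mask) -
    total_stock(est_cur, geom, mask)
  true_deficit <- total_stock(truth$potential_agc, geom, mask) -
    total_stock(truth$current_agc, geom, mask)
  list(r2 = r2, mean_bias = bias,
       deficit_rel_error = est_deficit / true_deficit - 1,
       true_deficit_gt = true_deficit, est_deficit_gt = est_deficit)
}
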