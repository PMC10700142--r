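#' Model specification for the counterfactual carbon models
#'
#' Four designs are supported. Type-1 designs (GS1, SD1) train on the full
#' human-disturbance gradient with the eight human covariates as
#' predictors and predict the potential by setting them to zero. Type-2
#' designs (GS2, SD2) train only on minimally disturbed pixels, without
#' human covariates. GS designs consume ground-sourced (inventory) pixel
#' observations; SD designs consume a carbon raster sampled at random
#' points. Spatial subsampling grids default to 0.7 degrees (GS1), 0.25
#' (GS2) and 1.0 (SD2); SD1 uses simple random sampling.
#'
#' @param design One of `"GS1"`, `"GS2"`, `"SD1"`, `"SD2"`.
#' @param n_bootstrap Ensemble size (>= 2).
#' @param subsample_grid_deg Spatial subsampling cell size in degrees;
#'   `NA` picks the per-design default.
#' @param hyperparameter_grid Data frame of candidate `num.trees`, `mtry`,
#'   `min.node.size` settings; `NULL` uses [default_hyper_grid()].
#' @param tune_each Re-run the grid search inside every bootstrap
#'   iteration instead of once on the first subsample.
#' @param sd_points Target sample size per bootstrap for SD designs.
#' @param seed Integer seed for the bootstrap.
#' @return A `model_spec` list.
#' @export
model_spec <- function(design = c("GS1", "GS2", "SD1", "SD2"),
                       n_bootstrap = 100, subsample_grid_deg = NA,
                       hyperparameter_grid = NULL, tune_each = FALSE,
                       sd_points = 1000, seed = 1) {
  design <- match.arg(design)
  if (n_bootstrap < 2) stop("n_bootstrap must be >= 2")
  if (is.na(subsample_grid_deg))
    subsample_grid_deg <- c(GS1 = 0.7, GS2 = 0.25, SD1 = NA, SD2 = 1.0)[[design]]
  if (!is.na(subsample_grid_deg) && subsample_grid_deg <= 0)
    stop("subsample grid size must be positive")
  if (is.null(hyperparameter_grid)) hyperparameter_grid <- default_hyper_grid()
  structure(list(design = design, n_bootstrap = as.integer(n_bootstrap),
                 subsample_grid_deg = subsample_grid_deg,
                 hyperparameter_grid = hyperparameter_grid,
                 tune_each = tune_each, sd_points = sd_points,
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Default hyperparameter grid
#'
#' Twelve candidate random-forest settings over tree count, candidate
#' features per split and minimum leaf size, searched by tenfold
#' cross-validation; a scaled-down grid with the same selection logic as
#' a large grid-search. The grid deliberately spans the regularized
#' (smooth-response) region: counterfactual prediction perturbs the
#' human-disturbance covariates away from their observed values, and very
#' deep trees overfit the disturbance boundary, inflating the contrast
#' between factual and counterfactual maps at lightly disturbed pixels.
#'
#' @return Data frame of settings.
#' @export
default_hyper_grid <- function() {
  expand.grid(num.trees = c(250, 500),
              mtry_frac = c(0.15, 0.33),
              min.node.size = c(10, 17, 25))
}

#' One-observation-per-cell spatial subsample
#'
#' Draws exactly one uniformly chosen row from every non-empty cell of a
#' regular lat/lon grid; the device used to even out spatially clustered
#' observations before model fitting.
#'
#' @param table Data frame with `lat` and `lon` columns.
#' @param grid_deg Cell size in degrees.
#' @return Subsampled data frame (row order follows cell order).
#' @export
spatial_subsample <- function(table, grid_deg) {
  if (is.null(table) || nrow(table) == 0) stop("empty table")
  stopifnot(grid_deg > 0)
  cell <- paste(floor(table$lat / grid_deg), floor(table$lon / grid_deg))
  idx <- unlist(lapply(split(seq_len(nrow(table)), cell), function(i)
    if (length(i) == 1L) i else sample(i, 1L)), use.names = FALSE)
  table[sort(idx), , drop = FALSE]
}

predictor_names <- function(table, design) {
  env <- grep("^env_", names(table), value = TRUE)
  human <- intersect(c("urban_built", "managed_veg", "cropland_use",
                       "grazing_use", "pasture_use", "rangeland_use",
                       "modification", "accessibility"), names(table))
  if (design %in% c("GS1", "SD1")) c(env, human, "canopy")
  else c(env, "canopy")
}

tune_ranger <- function(train, predictors, grid, n_folds = 10) {
  y <- train$carbon
  folds <- sample(rep_len(seq_len(n_folds), nrow(train)))
  score <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    mtry <- max(1L, round(grid$mtry_frac[g] * length(predictors)))
    pred <- numeric(nrow(train))
    for (f in seq_len(n_folds)) {
      tr <- train[folds != f, , drop = FALSE]
      fit <- ranger::ranger(
        x = tr[predictors], y = tr$carbon,
        num.trees = grid$num.trees[g], mtry = mtry,
        min.node.size = grid$min.node.size[g],
        num.threads = 1, seed = 1)
      pred[folds == f] <-
        stats::predict(fit, train[folds == f, predictors, drop = FALSE],
                       num.threads = 1)$predictions
    }
    score[g] <- r2_one_to_one(y, pred)
  }
  list(best = which.max(score), scores = score)
}

#' Fit one current-carbon regressor
#'
#' Random-forest regression of pixel carbon on the design's covariate
#' block (environment + human disturbance + canopy for type 1;
#' environment + canopy on minimally disturbed rows only for type 2).
#' Hyperparameters are chosen as the setting with the highest tenfold
#' cross-validated score against the 1:1 line over the configured grid.
#'
#' @param subsample Training rows (already spatially subsampled for
#'   GS1/GS2/SD2, simple random for SD1) with a `carbon` column.
#' @param spec A [model_spec()].
#' @param hyper Optionally a pre-chosen row index of the grid; `NULL`
#'   triggers the grid search.
#' @return List with the fitted `ranger` model, `predictors`, the chosen
#'   grid row and the CV scores (when tuned).
#' @export
fit_current_model <- function(subsample, spec, hyper = NULL) {
  if (spec$design %in% c("GS2", "SD2")) {
    if (!is.null(subsample$minimal))
      subsample <- subsample[subsample$minimal, , drop = FALSE]
  }
  if (nrow(subsample) < 50)
    stop("fewer than 50 training rows; fit would be unstable")
  predictors <- predictor_names(subsample, spec$design)
  grid <- spec$hyperparameter_grid
  scores <- NULL
  if (is.null(hyper)) {
    tuned <- tune_ranger(subsample, predictors, grid)
    hyper <- tuned$best
    scores <- tuned$scores
  }
  mtry <- max(1L, round(grid$mtry_frac[hyper] * length(predictors)))
  fit <- ranger::ranger(
    x = subsample[predictors], y = subsample$carbon,
    num.trees = grid$num.trees[hyper], mtry = mtry,
    min.node.size = grid$min.node.size[hyper],
    num.threads = 1, seed = 1)
  list(model = fit, predictors = predictors, design = spec$design,
       hyper = hyper, cv_scores = scores, n_train = nrow(subsample))
}

#' Fit the bootstrap ensemble
#'
#' Repeats spatial subsampling (or simple random sampling for SD1) and
#' model fitting `n_bootstrap` times. By default hyperparameters are tuned
#' once on the first subsample and reused; `tune_each = TRUE` re-runs the
#' grid search per iteration.
#'
#' @param table Training table from [build_training_table()] (GS designs)
#'   or [sd_training_table()] (SD designs).
#' @param spec A [model_spec()].
#' @return An `carbon_ensemble` list of fitted members.
#' @export
fit_ensemble <- function(table, spec) {
  set.seed(spec$seed)
  members <- vector("list", spec$n_bootstrap)
  hyper <- NULL
  for (b in seq_len(spec$n_bootstrap)) {
    sub <- if (spec$design == "SD1") {
      n <- min(spec$sd_points, nrow(table))
      table[sample.int(nrow(table), n, replace = TRUE), , drop = FALSE]
    } else {
      spatial_subsample(table, spec$subsample_grid_deg)
    }
    m <- fit_current_model(sub, spec, hyper = hyper)
    if (!spec$tune_each && is.null(hyper)) hyper <- m$hyper
    members[[b]] <- m
  }
  structure(list(members = members, spec = spec), class = "carbon_ensemble")
}

ensemble_predict_table <- function(ensemble, newdata) {
  sapply(ensemble$members, function(m)
    stats::predict(m$model, newdata[m$predictors],
                   num.threads = 1)$predictions)
}

summarize_ensemble <- function(pred_mat, geom, mask = NULL) {
  mean_v <- rowMeans(pred_mat)
  sd_v <- apply(pred_mat, 1, stats::sd)
  shape <- function(v) matrix(v, geom$nrow, geom$ncol)
  out <- list(
    mean = shape(mean_v),
    cv = shape(ifelse(mean_v > 0, sd_v / mean_v, 0)),
    q05 = shape(apply(pred_mat, 1, stats::quantile, probs = 0.05)),
    q95 = shape(apply(pred_mat, 1, stats::quantile, probs = 0.95))
  )
  if (!is.null(mask)) out <- lapply(out, function(m) { m[!mask] <- NA; m })
  structure(out, class = "ensemble_prediction")
}

#' Counterfactual potential-carbon prediction
#'
#' Predicts each ensemble member on the full pixel grid with the human
#' covariates set to zero (type-1 designs) or with the as-fitted covariate
#' set (type-2), and the canopy covariate replaced by potential canopy
#' cover. Predictions are masked to pixels that would naturally support
#' trees (potential canopy >= 10%).
#'
#' @param ensemble A [fit_ensemble()] result.
#' @param stack A [generate_covariates()] stack.
#' @param potential_canopy Matrix of potential canopy cover; required.
#' @return An `ensemble_prediction` with `mean`, `cv`, `q05`, `q95` rasters.
#' @export
predict_potential <- function(ensemble, stack, potential_canopy) {
  if (missing(potential_canopy) || is.null(potential_canopy))
    stop("potential canopy layer is required")
  type1 <- ensemble$spec$design %in% c("GS1", "SD1")
  newdata <- pixel_table(stack, potential_canopy, zero_human = type1)
  pred <- ensemble_predict_table(ensemble, newdata)
  summarize_ensemble(pred, stack$geom, mask = potential_canopy >= 0.10)
}

#' Current-carbon prediction
#'
#' Ensemble prediction with observed covariates and current canopy.
#'
#' @inheritParams predict_potential
#' @param current_canopy Matrix of current canopy cover.
#' @param mask Optional logical matrix restricting the output.
#' @return An `ensemble_prediction`.
#' @export
predict_current <- function(ensemble, stack, current_canopy, mask = NULL) {
  newdata <- pixel_table(stack, current_canopy, zero_human = FALSE)
  pred <- ensemble_predict_table(ensemble, newdata)
  summarize_ensemble(pred, stack$geom, mask = mask)
}

#' Training table for satellite-derived designs
#'
#' Samples pixel carbon directly from a current-carbon raster (standing in
#' for a satellite product) instead of inventory plots.
#'
#' @param carbon Matrix of current carbon (t C/ha, pixel scale).
#' @param stack A [generate_covariates()] stack.
#' @param current_canopy Matrix of current canopy cover.
#' @return Data frame shaped like [build_training_table()] output.
#' @export
sd_training_table <- function(carbon, stack, current_canopy) {
  geom <- stack$geom
  tab <- pixel_table(stack, current_canopy, zero_human = FALSE)
  tab$carbon <- as.numeric(carbon)
  tab$minimal <- as.numeric(stack$minimal_disturbance) > 0
  tab$lat <- geom$lat[tab$row]
  tab$lon <- geom$lon[tab$col]
  tab[stats::complete.cases(tab), , drop = FALSE]
}

#' Scale aboveground carbon to whole-plant carbon via root mass fraction
#'
#' With RMF defined as root mass over total plant mass, total living
#' carbon is `agc / (1 - rmf)`. Bounds combine the aboveground range with
#' the RMF range by endpoint evaluation (the expression is monotone in
#' both arguments). A `direct` mode multiplying by `(1 + rmf)` is kept
#' behind a switch.
#'
#' @param agc Aboveground carbon (matrix or vector), t C/ha.
#' @param rmf Root mass fraction in `[0, 1)`.
#' @param agc_lo,agc_hi Optional aboveground bounds (default `agc`).
#' @param rmf_lo,rmf_hi Optional RMF bounds (default `rmf`).
#' @param mode `"fraction"` (default) or `"direct"`.
#' @return List with `mean`, `lo`, `hi` total living carbon.
#' @export
add_root_carbon <- function(agc, rmf, agc_lo = agc, agc_hi = agc,
                            rmf_lo = rmf, rmf_hi = rmf,
                            mode = c("fraction", "direct")) {
  mode <- match.arg(mode)
  if (any(rmf_hi >= 1)) stop("root mass fraction must be < 1")
  if (any(rmf_lo < 0)) stop("root mass fraction must be >= 0")
  f <- if (mode == "fraction") function(a, r) a / (1 - r)
       else function(a, r) a * (1 + r)
  list(mean = f(agc, rmf), lo = f(agc_lo, rmf_lo), hi = f(agc_hi, rmf_hi))
}

#' Total carbon stock of a raster
#'
#' `sum(density * pixel_area)` over masked pixels, in Gt C. Pixel areas
#' carry the cosine-latitude correction of [pixel_area_ha()].
#'
#' @param density Matrix of carbon density, t C/ha; `NA` pixels ignored.
#' @param geom A [grid_geometry()].
#' @param mask Optional logical matrix.
#' @return Stock in Gt C.
#' @export
total_stock <- function(density, geom, mask = NULL) {
  if (any(density < 0, na.rm = TRUE)) stop("negative carbon density")
  area <- pixel_area_ha(geom)
  v <- density * area
  if (!is.null(mask)) v[!mask] <- NA
  sum(v, na.rm = TRUE) / 1e9
}
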