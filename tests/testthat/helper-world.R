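# Shared small-world fixture, built once per test run and memoised.
# 64x64 keeps every stage exercised (all four biome bands, water, ice,
# converted land, minimal-disturbance area) at a few seconds of runtime.

.world_cache <- new.env(parent = emptyenv())

small_world <- function(seed = 3, gamma = 1) {
  key <- paste0("w", seed, "_", gamma)
  if (!is.null(.world_cache[[key]])) return(.world_cache[[key]])
  cfg <- world_config(grid_height = 64, grid_width = 64,
                      lat_range = c(-32, 32), lon_range = c(-32, 32),
                      gamma_degradation = gamma, smooth_sigma = 4,
                      plot_density = 8, seed = seed)
  w <- synthesize_world(cfg)
  .world_cache[[key]] <- w
  w
}

small_training <- function(seed = 3) {
  key <- paste0("t", seed)
  if (!is.null(.world_cache[[key]])) return(.world_cache[[key]])
  w <- small_world(seed)
  plots <- plot_carbon_table(w$trees, w$stack, w$truth$current_canopy)
  pixels <- apply_plot_filters(plots)
  train <- build_training_table(pixels, w$stack, w$truth$current_canopy)
  .world_cache[[key]] <- list(world = w, plots = plots, pixels = pixels,
                              train = train)
  .world_cache[[key]]
}

# covariate set whose correlation structure needs exactly 19 principal
# components for 90% of the variance: 19 latent factors observed directly
# plus 15 noisy duplicates (loading 0.8), giving correlation eigenvalues
# 15 x 1.8, 4 x 1.0, 15 x 0.2 -> cumulative 88.2% at 18, 91.2% at 19
hull_fixture <- function(n = 4000) {
  f <- matrix(rnorm(n * 19), ncol = 19)
  dup <- 0.8 * f[, 1:15] + 0.6 * matrix(rnorm(n * 15), ncol = 15)
  cbind(f, dup)
}

# simple deterministic learner for cross-validation tests: ranger with a
# fixed seed wrapped as a model factory
rf_factory <- function(predictors, num.trees = 100) {
  function(train) {
    fit <- ranger::ranger(x = train[predictors], y = train$carbon,
                          num.trees = num.trees, mtry = max(1, length(predictors) %/% 2),
                          min.node.size = 5, seed = 1, num.threads = 1)
    function(newdata)
      stats::predict(fit, newdata[predictors], num.threads = 1)$predictions
  }
}
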