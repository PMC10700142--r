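test_that("spatial subsample keeps one row per occupied cell", {
  one_cell <- data.frame(lat = runif(20, 0, 0.5), lon = runif(20, 0, 0.5))
  expect_equal(nrow(spatial_subsample(one_cell, 0.7)), 1)

  lattice <- expand.grid(lat = seq(0.35, 6.65, by = 0.7),
                         lon = seq(0.35, 6.65, by = 0.7))
  expect_equal(nrow(spatial_subsample(lattice, 0.7)), nrow(lattice))
  expect_error(spatial_subsample(data.frame()), "empty")
})

test_that("spatial subsample matches a brute-force binning oracle", {
  set.seed(21)
  n <- 1000
  centers <- matrix(runif(20, -20, 20), ncol = 2)
  pick <- sample(10, n, replace = TRUE)
  tab <- data.frame(lat = centers[pick, 1] + rnorm(n, sd = 1.5),
                    lon = centers[pick, 2] + rnorm(n, sd = 1.5))
  sub <- spatial_subsample(tab, 0.7)
  cell_of <- function(d) paste(floor(d$lat / 0.7), floor(d$lon / 0.7))
  # oracle: occupied cells counted independently
  expect_equal(nrow(sub), length(unique(cell_of(tab))))
  expect_false(any(duplicated(cell_of(sub))))
  # every selected row is a member of its cell in the source table
  expect_true(all(cell_of(sub) %in% cell_of(tab)))
})

test_that("the regressor learns a noiseless linear response", {
  set.seed(31)
  n <- 400
  tab <- data.frame(lat = runif(n, -10, 10), lon = runif(n, -10, 10))
  for (i in 1:6) tab[[sprintf("env_%02d", i)]] <- rnorm(n)
  tab$canopy <- runif(n)
  tab$carbon <- 50 + 20 * tab$env_01 - 10 * tab$env_02 + 100 * tab$canopy
  tab$minimal <- TRUE
  spec <- model_spec("GS1", n_bootstrap = 2, seed = 1)
  fit <- fit_current_model(tab, spec)
  pred <- predict(fit$model, tab[fit$predictors], num.threads = 1)$predictions
  expect_gt(r2_one_to_one(tab$carbon, pred), 0.95)
  expect_error(fit_current_model(tab[1:20, ], spec), "50")
})

test_that("type-2 designs train only on minimally disturbed rows", {
  tw <- small_training()
  spec <- model_spec("GS2", n_bootstrap = 2, seed = 2)
  sub <- spatial_subsample(tw$train, spec$subsample_grid_deg)
  fit <- fit_current_model(sub, spec, hyper = 1)
  expect_equal(fit$n_train, sum(sub$minimal))
  expect_false("modification" %in% fit$predictors)
  # type-1 uses the human block
  spec1 <- model_spec("GS1", n_bootstrap = 2, seed = 2)
  fit1 <- fit_current_model(sub, spec1, hyper = 1)
  expect_true(all(c("modification", "urban_built") %in% fit1$predictors))
})

test_that("grid search picks the argmax of independently recomputed scores", {
  set.seed(41)
  n <- 220
  tab <- data.frame(lat = runif(n), lon = runif(n))
  for (i in 1:5) tab[[sprintf("env_%02d", i)]] <- rnorm(n)
  tab$canopy <- runif(n)
  tab$carbon <- 30 * tab$env_01 + 50 * tab$canopy + rnorm(n, sd = 5)
  tab$minimal <- TRUE
  grid <- expand.grid(num.trees = c(50, 150), mtry_frac = c(0.3, 0.8),
                      min.node.size = 5)
  spec <- model_spec("GS1", n_bootstrap = 2, seed = 7,
                     hyperparameter_grid = grid)
  set.seed(7)
  fit <- fit_current_model(tab, spec)
  # naive re-run of the same tenfold loop under the same fold RNG
  predictors <- fit$predictors
  set.seed(7)
  folds <- sample(rep_len(1:10, n))
  score <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    mtry <- max(1L, round(grid$mtry_frac[g] * length(predictors)))
    pred <- numeric(n)
    for (f in 1:10) {
      m <- ranger::ranger(x = tab[folds != f, predictors],
                          y = tab$carbon[folds != f],
                          num.trees = grid$num.trees[g], mtry = mtry,
                          min.node.size = grid$min.node.size[g],
                          seed = 1, num.threads = 1)
      pred[folds == f] <- predict(m, tab[folds == f, predictors],
                                  num.threads = 1)$predictions
    }
    score[g] <- r2_one_to_one(tab$carbon, pred)
  }
  expect_equal(fit$hyper, which.max(score))
  expect_equal(fit$cv_scores, score, tolerance = 1e-12)
})

test_that("ensemble prediction is reproducible and permutation-invariant", {
  tw <- small_training()
  st <- tw$world$stack
  tr <- tw$world$truth
  spec <- model_spec("GS1", n_bootstrap = 3, seed = 5,
                     hyperparameter_grid = data.frame(
                       num.trees = 100, mtry_frac = 0.33, min.node.size = 10))
  e1 <- fit_ensemble(tw$train, spec)
  e2 <- fit_ensemble(tw$train, spec)
  p1 <- predict_potential(e1, st, tr$potential_canopy)
  p2 <- predict_potential(e2, st, tr$potential_canopy)
  expect_identical(p1$mean, p2$mean)
  # member order does not change the ensemble mean
  e3 <- e1
  e3$members <- rev(e3$members)
  p3 <- predict_potential(e3, st, tr$potential_canopy)
  expect_equal(p3$mean, p1$mean)
  expect_error(predict_potential(e1, st, NULL), "required")
})

test_that("the type-1 counterfactual is the identity where humans are absent", {
  tw <- small_training()
  st <- tw$world$stack
  tr <- tw$world$truth
  spec <- model_spec("GS1", n_bootstrap = 2, seed = 5,
                     hyperparameter_grid = data.frame(
                       num.trees = 100, mtry_frac = 0.33, min.node.size = 10))
  ens <- fit_ensemble(tw$train, spec)
  pot <- predict_potential(ens, st, tr$potential_canopy)
  cur <- predict_current(ens, st, tr$current_canopy)
  hzero <- Reduce(pmax, st$human) == 0
  lczero <- st$landcover$water + st$landcover$ice == 0
  idx <- which(hzero & lczero & tr$potential_canopy >= 0.10)
  expect_gt(length(idx), 50)
  # identical covariate vectors -> identical forest predictions
  expect_equal(pot$mean[idx], cur$mean[idx], tolerance = 1e-12)
})

test_that("an ensemble of identical members has zero coefficient of variation", {
  tw <- small_training()
  st <- tw$world$stack
  tr <- tw$world$truth
  spec <- model_spec("GS1", n_bootstrap = 2, seed = 5,
                     hyperparameter_grid = data.frame(
                       num.trees = 50, mtry_frac = 0.33, min.node.size = 10))
  ens <- fit_ensemble(tw$train, spec)
  ens$members <- list(ens$members[[1]], ens$members[[1]])
  pot <- predict_potential(ens, st, tr$potential_canopy)
  expect_true(all(pot$cv[!is.na(pot$cv)] == 0))
})

test_that("root scaling follows the chosen convention with monotone bounds", {
  expect_equal(add_root_carbon(100, 0)$mean, 100)
  expect_equal(add_root_carbon(100, 0.5)$mean, 200)
  out <- add_root_carbon(100, 0.25, agc_lo = 90, agc_hi = 110,
                         rmf_lo = 0.20, rmf_hi = 0.30)
  # brute-force endpoint enumeration
  grid <- expand.grid(a = c(90, 110), r = c(0.20, 0.30))
  vals <- grid$a / (1 - grid$r)
  expect_equal(out$lo, min(vals))
  expect_equal(out$hi, max(vals))
  expect_equal(add_root_carbon(100, 0.25, mode = "direct")$mean, 125)
  expect_error(add_root_carbon(100, 1.0), "< 1")
})

test_that("total stock matches an explicit cos-latitude loop", {
  geom <- grid_geometry(20, 15, c(30, 50), c(-10, 5))
  set.seed(8)
  dens <- matrix(runif(300, 0, 200), 20, 15)
  mask <- matrix(runif(300) > 0.4, 20, 15)
  # independent per-pixel loop
  acc <- 0
  for (i in 1:20) for (j in 1:15) {
    if (!mask[i, j]) next
    cell_km2 <- (1 * 111.32) * (1 * 111.32) * cos(geom$lat[i] * pi / 180)
    acc <- acc + dens[i, j] * cell_km2 * 100
  }
  expect_equal(total_stock(dens, geom, mask), acc / 1e9, tolerance = 1e-12)
  expect_equal(total_stock(dens, geom, matrix(FALSE, 20, 15)), 0)
  expect_error(total_stock(-dens, geom), "negative")
})
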