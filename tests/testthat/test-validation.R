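test_that("the 1:1-line score matches hand arithmetic", {
  o <- c(1, 2, 3)
  expect_equal(r2_one_to_one(o, o), 1)
  expect_equal(r2_one_to_one(o, rep(mean(o), 3)), 0)
  expect_equal(r2_one_to_one(o, c(1, 2, 4)), 0.5)
  expect_error(r2_one_to_one(c(2, 2), c(1, 2)), "variance")
})

test_that("Moran's I matches a brute-force double sum on a hand example", {
  coords <- data.frame(lon = c(0, 0.4, 0.1, 0.5), lat = c(0, 0, 0.4, 0.4))
  z <- c(1.2, -0.7, 0.4, -0.9)
  bins <- c(0, 60, 120)
  set.seed(1)
  res <- morans_i(z, coords, distance_bins = bins, n_perm = 49)
  d <- geosphere::distm(as.matrix(coords), fun = geosphere::distHaversine) / 1000
  zc <- z - mean(z)
  for (b in 1:2) {
    w <- matrix(0, 4, 4)
    s0 <- 0; num <- 0
    for (i in 1:4) for (j in 1:4) {
      if (i == j) next
      if (d[i, j] > bins[b] && d[i, j] <= bins[b + 1]) {
        s0 <- s0 + 1
        num <- num + zc[i] * zc[j]
      }
    }
    if (s0 > 0)
      expect_equal(res$moran_i[b], 4 / s0 * num / sum(zc^2), tolerance = 1e-12)
  }
  expect_equal(unique(res$expected_i), -1 / 3)
})

test_that("Moran's I separates white noise from a smooth field", {
  set.seed(17)
  n <- 150
  lon <- runif(n, 0, 8); lat <- runif(n, 0, 8)
  iid <- rnorm(n)
  res_iid <- morans_i(iid, data.frame(lon = lon, lat = lat),
                      distance_bins = seq(0, 600, by = 100), n_perm = 99)
  expect_true(all(res_iid$p_value[1:3] > 0.05, na.rm = TRUE))

  # smooth field: value = filtered surface evaluated at the points
  f <- smooth_gaussian(matrix(rnorm(64 * 64), 64, 64), 6)
  gi <- pmin(64, pmax(1, ceiling(lat / 8 * 64)))
  gj <- pmin(64, pmax(1, ceiling(lon / 8 * 64)))
  sm <- f[cbind(gi, gj)] * 10
  res_sm <- morans_i(sm, data.frame(lon = lon, lat = lat),
                     distance_bins = seq(0, 600, by = 100), n_perm = 99)
  expect_gt(res_sm$moran_i[1], 0)
  expect_lt(res_sm$p_value[1], 0.05)
  expect_error(morans_i(rep(1, 20), data.frame(lon = 1:20, lat = 1:20)),
               "variance")
})

test_that("buffered LOO-CV with zero buffer equals classical LOO", {
  set.seed(23)
  n <- 60
  tab <- data.frame(lat = runif(n, 0, 5), lon = runif(n, 0, 5),
                    env_01 = rnorm(n))
  tab$carbon <- 3 * tab$env_01 + rnorm(n, sd = 0.3)
  # deterministic learner: OLS on env_01
  factory <- function(train) {
    fit <- lm(carbon ~ env_01, data = train)
    function(newdata) predict(fit, newdata)
  }
  b0 <- buffered_loocv(tab, factory, buffer_km = 0)
  loo <- vapply(seq_len(n), function(i) {
    fit <- lm(carbon ~ env_01, data = tab[-i, ])
    predict(fit, tab[i, , drop = FALSE])
  }, numeric(1))
  expect_equal(b0$predictions, unname(loo), tolerance = 1e-12)
  expect_equal(b0$r2, r2_one_to_one(tab$carbon, loo))
  # identical rerun for a deterministic factory
  expect_identical(b0$predictions,
                   buffered_loocv(tab, factory, buffer_km = 0)$predictions)
  expect_error(buffered_loocv(tab, factory, buffer_km = 1e6), "excludes")
})

test_that("buffered CV is no more optimistic than random k-fold CV", {
  # autocorrelated response sampled from a smooth surface: proximity leaks
  # into random folds but is blocked by the buffer
  set.seed(29)
  f <- smooth_gaussian(matrix(rnorm(80 * 80), 80, 80), 8)
  n <- 110
  gi <- sample(80, n, replace = TRUE); gj <- sample(80, n, replace = TRUE)
  tab <- data.frame(lat = gi / 80 * 6, lon = gj / 80 * 6)
  tab$env_01 <- smooth_gaussian(matrix(rnorm(80 * 80), 80, 80), 8)[cbind(gi, gj)]
  tab$carbon <- 100 + 40 * f[cbind(gi, gj)] + 10 * tab$env_01 + rnorm(n)
  factory <- rf_factory(c("lat", "lon", "env_01"))
  buf <- buffered_loocv(tab, factory, buffer_km = 120)
  set.seed(30)
  kf <- kfold_cv(tab, factory, k = 10)
  expect_lte(buf$r2, kf$r2)
})

test_that("hull coverage counts pairs and classifies points correctly", {
  set.seed(37)
  tr <- matrix(rnorm(400 * 6), ncol = 6)
  hd <- hull_coverage(tr, tr[1:50, , drop = FALSE], variance_target = 0.90)
  expect_equal(hd$n_hulls, hd$n_components * (hd$n_components - 1) / 2)
  # training points are vertices or interior points of every hull
  expect_true(all(hd$inside_fraction == 1))

  far <- tr[1:5, , drop = FALSE]
  far[, 1] <- far[, 1] + 10 * diff(range(tr[, 1]))
  hd2 <- hull_coverage(tr, far)
  expect_true(all(hd2$inside_fraction < 0.95))
})

test_that("retaining 19 components yields exactly 171 pairwise hulls", {
  set.seed(43)
  x <- hull_fixture()
  hd <- hull_coverage(x, x[1:20, , drop = FALSE], variance_target = 0.90)
  expect_equal(hd$n_components, 19)
  expect_equal(hd$n_hulls, 171)
})

test_that("hull coverage is invariant to affine rescaling of covariates", {
  set.seed(47)
  tr <- matrix(rnorm(300 * 5), ncol = 5)
  px <- matrix(rnorm(40 * 5, sd = 2), ncol = 5)
  h1 <- hull_coverage(tr, px)
  scl <- c(10, 0.2, 5, 100, 3)
  shift <- c(-4, 2, 0, 50, 1)
  tr2 <- sweep(sweep(tr, 2, scl, "*"), 2, shift, "+")
  px2 <- sweep(sweep(px, 2, scl, "*"), 2, shift, "+")
  h2 <- hull_coverage(tr2, px2)
  expect_equal(h1$inside_fraction, h2$inside_fraction, tolerance = 1e-9)
})

test_that("partial regression recovers the degradation signal", {
  # plot-level carbon observations along the disturbance gradient,
  # controlling for all environmental layers at the plot pixels
  run_pr <- function(gamma) {
    w <- small_world(seed = 3, gamma = gamma)
    p <- plot_carbon_table(w$trees, w$stack, w$truth$current_canopy)
    ij <- cbind(p$row, p$col)
    keep <- p$carbon_density > 0
    env <- sapply(w$stack$env, function(m) m[ij])
    hum <- sapply(w$stack$human, function(m) m[ij])
    disturbance_partial_regression(p$carbon_density[keep],
                                   env[keep, ], hum[keep, ])
  }
  pr1 <- run_pr(1)
  expect_lt(pr1$slope, 0)
  expect_lt(pr1$conf_int[2], 0)  # significantly negative under degradation

  pr0 <- run_pr(0)
  expect_gt(pr0$conf_int[2], 0)  # CI covers zero without degradation
  expect_lt(pr0$conf_int[1], 0)
})

test_that("partial slope equals the simple slope under orthogonality", {
  set.seed(53)
  n <- 300
  env <- matrix(rnorm(n * 3), ncol = 3)
  pc_true <- rnorm(n)
  # eight human layers sharing one orthogonal factor
  hum <- sapply(1:8, function(j) 0.9 * pc_true + 0.1 * rnorm(n))
  hum <- pmax(hum, 0)
  carbon <- 100 - 5 * rowMeans(hum) + rnorm(n, sd = 0.5)
  pr <- disturbance_partial_regression(carbon, env, hum)
  pca <- prcomp(hum, center = TRUE, scale. = TRUE)
  pc1 <- pca$x[, 1] * sign(sum(pca$rotation[, 1]))
  simple <- coef(lm(I(carbon / mean(carbon)) ~ pc1))[2]
  expect_equal(pr$slope, unname(simple), tolerance = 0.02)
})

test_that("surface residuals have mean zero and reduced variance", {
  tw <- small_training()
  res <- surface_residuals(tw$train)
  expect_equal(mean(res), 0, tolerance = 1e-8)
  expect_lt(var(res), var(tw$train$carbon))
})
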