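test_that("log-log biomass prediction matches the closed form", {
  expect_equal(predict_biomass(1, allometric_equation(0, 2.4)), 1)
  expect_equal(predict_biomass(10, allometric_equation(0, 2)), 100)
  expect_equal(predict_biomass(30, allometric_equation(-2.0, 2.4)),
               exp(-2.0 + 2.4 * log(30)))
  eq <- allometric_equation(-2.3, 2.45)
  d <- seq(5, 300, length.out = 50)
  expect_true(all(diff(predict_biomass(d, eq)) > 0))
  expect_error(predict_biomass(0, eq), "positive")
  expect_error(allometric_equation(0, -1), "beta1")
})

test_that("tropical power law is homogeneous and falls back on density", {
  # doubling density multiplies biomass by 2^b
  b <- 0.976
  w1 <- predict_biomass_tropical(25, 0.3)
  w2 <- predict_biomass_tropical(25, 0.6)
  expect_equal(w2 / w1, 2^b)
  expect_equal(predict_biomass_tropical(10, 0.5, coeffs = c(a = 1, b = 1)), 50)
  expect_equal(predict_biomass_tropical(25, 0.6),
               0.0673 * (0.6 * 25^2)^0.976)
  expect_message(wf <- predict_biomass_tropical(25, NA_real_), "median")
  expect_equal(wf, predict_biomass_tropical(25, 0.6))
})

test_that("pseudo-data grid follows the three diameter bins", {
  eq <- allometric_equation(-2.2, 2.4)
  pd <- generate_pseudo_data(eq)
  expect_equal(nrow(pd), 56)            # 21 + 15 + 20
  expect_equal(min(pd$dbh), 5)
  expect_equal(max(pd$dbh), 300)
  expect_false(any(duplicated(pd$dbh)))
  expect_equal(sum(pd$dbh <= 25), 21)
  expect_equal(sum(pd$dbh > 25 & pd$dbh <= 100), 15)
  # noiseless back-calculation: points sit exactly on the generating line
  fit <- lm(log(biomass) ~ log(dbh), data = pd)
  expect_equal(suppressWarnings(summary(fit)$r.squared), 1)
})

test_that("biome refit recovers and interpolates source equations", {
  eq <- allometric_equation(-2.35, 2.42)
  refit <- fit_biome_equation(generate_pseudo_data(eq))
  expect_equal(refit$beta0, eq$beta0, tolerance = 1e-10)
  expect_equal(refit$beta1, eq$beta1, tolerance = 1e-10)

  pooled <- rbind(generate_pseudo_data(allometric_equation(-2.2, 2.2)),
                  generate_pseudo_data(allometric_equation(-2.2, 2.6)))
  mid <- fit_biome_equation(pooled)
  expect_gt(mid$beta1, 2.2)
  expect_lt(mid$beta1, 2.6)
  # independent brute-force OLS on the pooled grid
  x <- log(pooled$dbh); y <- log(pooled$biomass)
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(mid$beta1, b1, tolerance = 1e-12)

  expect_error(fit_biome_equation(data.frame()), "empty")
  one <- data.frame(dbh = c(10, 10), biomass = c(50, 60))
  expect_error(fit_biome_equation(one), "degenerate")
})

test_that("plot carbon density follows the unit arithmetic", {
  # one 500-kg tree on 250 m2 at carbon fraction 0.5 -> 10 t C / ha
  eq <- allometric_equation(log(500), 1e-9)   # flat law: every tree 500 kg
  trees <- data.frame(dbh_cm = 1, year = 2000)
  pc <- plot_carbon_density(trees, 250, eq, carbon_fraction = 0.5)
  expect_equal(pc$carbon_density, 10)

  expect_equal(plot_carbon_density(NULL, 250, eq)$carbon_density, 0)

  # two visits in different years are averaged per calendar year
  eq2 <- allometric_equation(0, 2)
  t2 <- data.frame(dbh_cm = c(10, 10, 10), year = c(2000, 2001, 2001))
  d_one <- 100 / 1000 / 0.025           # one 100-kg tree, no carbon fraction
  pc2 <- plot_carbon_density(t2, 250, eq2, carbon_fraction = 1)
  expect_equal(pc2$carbon_density, mean(c(d_one, 2 * d_one)))
})

test_that("plot carbon is order-invariant and additive over tree sets", {
  eq <- allometric_equation(-2.3, 2.4)
  set.seed(7)
  trees <- data.frame(dbh_cm = runif(40, 5, 80), year = 2000)
  a <- plot_carbon_density(trees, 250, eq)$carbon_density
  b <- plot_carbon_density(trees[sample(40), , drop = FALSE], 250, eq)$carbon_density
  expect_equal(a, b)
  s1 <- plot_carbon_density(trees[1:15, , drop = FALSE], 250, eq)$carbon_density
  s2 <- plot_carbon_density(trees[16:40, , drop = FALSE], 250, eq)$carbon_density
  expect_equal(a, s1 + s2)
})

test_that("MAD filter matches its definition on the worked example", {
  x <- c(1, 2, 3, 4, 100)
  keep <- mad_filter(x, k = 2.5, transform = TRUE)
  expect_equal(keep, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_true(all(mad_filter(rep(7, 10))))
  expect_true(all(mad_filter(x, k = 1e9)))
  # zero MAD keeps only the median value
  expect_equal(mad_filter(c(5, 5, 5, 9)), c(TRUE, TRUE, TRUE, FALSE))
})

test_that("MAD filter agrees with a brute-force reference on random input", {
  brute <- function(v, k, transform) {
    t <- if (transform) log(v + 1) else v
    m <- sort(t)[ceiling(length(t) / 2)]          # lower median
    if (length(t) %% 2 == 0)
      m <- mean(sort(t)[length(t) / 2 + c(0, 1)])
    dev <- abs(t - m)
    md <- sort(dev)[ceiling(length(dev) / 2)]
    if (length(dev) %% 2 == 0)
      md <- mean(sort(dev)[length(dev) / 2 + c(0, 1)])
    dev <= k * md
  }
  set.seed(11)
  for (i in 1:1000) {
    v <- rlnorm(sample(5:30, 1), meanlog = 3, sdlog = 1.2)
    k <- runif(1, 0.5, 4)
    tf <- runif(1) < 0.5
    expect_identical(mad_filter(v, k, tf), brute(v, k, tf))
  }
})

test_that("plot filters enforce the density cap and the non-forest exception", {
  base <- data.frame(
    plot_id = 1:12, row = 1:12, col = 1L, biome = "temperate",
    carbon_density = c(100, 110, 105, 95, 102, 98, 103, 97, 2000, 0.01, 0.01, 104),
    human_index = c(rep(0, 9), 0.5, 0.0, 0),
    canopy_pixel = c(rep(0.8, 9), 0.05, 0.9, 0.8))
  out <- apply_plot_filters(base)
  # the 2000 t C/ha plot always falls to the absolute cap
  expect_false(2000 %in% out$carbon_density)
  # low-side outlier in a human-modified non-forest pixel is kept ...
  expect_true(10 %in% out$row)
  # ... but the same value in an undisturbed forested pixel is removed
  expect_false(11 %in% out$row)

  outside <- base[1:2, ]; outside$row <- NA_integer_
  expect_warning(apply_plot_filters(rbind(base, outside)), "outside")
})

test_that("co-located plots are averaged after filtering", {
  plots <- data.frame(
    plot_id = 1:4, row = c(1, 1, 2, 2), col = 1L, biome = "tropical",
    carbon_density = c(10, 20, 50, 60),
    human_index = 0, canopy_pixel = 0.7)
  out <- apply_plot_filters(plots)
  expect_equal(nrow(out), 2)
  expect_equal(sort(out$carbon_density), c(15, 55))
  expect_equal(sort(out$n_plots), c(2, 2))
})
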