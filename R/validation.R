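#' Coefficient of determination relative to the 1:1 line
#'
#' `1 - sum((o - p)^2) / sum((o - mean(o))^2)`; a standardized mean
#' squared error that penalizes bias as well as scatter, and can be
#' negative when predictions do worse than the observed mean.
#'
#' @param observed,predicted Equal-length numeric vectors (n >= 2).
#' @return The score.
#' @export
r2_one_to_one <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observed values have zero variance")
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Moran's I of residuals in distance bands
#'
#' Standard Moran's I with binary distance-band weights per bin,
#' `I = n / S0 * sum_ij w_ij z_i z_j / sum_i z_i^2`, with great-circle
#' (haversine) distances. Significance per bin by permutation of the
#' residuals.
#'
#' @param residuals Centred numeric vector (n >= 10).
#' @param coords Data frame or matrix with `lon`, `lat` columns (degrees).
#' @param distance_bins Increasing vector of bin edges in km (first edge
#'   typically 0).
#' @param n_perm Number of permutations for p-values.
#' @return A `moran_result` data frame with one row per band: `from_km`,
#'   `to_km`, `moran_i`, `expected_i`, `p_value`, `n_pairs`; attribute
#'   `autocorrelation_range_km` holds the lower edge of the first band in
#'   which I is not significantly positive.
#' @export
morans_i <- function(residuals, coords, distance_bins = seq(0, 1000, by = 20),
                     n_perm = 199) {
  n <- length(residuals)
  stopifnot(n >= 3, nrow(coords) == n)
  if (stats::sd(residuals) == 0) stop("zero-variance residuals")
  coords <- as.matrix(coords[, c("lon", "lat")])
  d_km <- geosphere::distm(coords, fun = geosphere::distHaversine) / 1000
  z <- residuals - mean(residuals)
  denom <- sum(z^2)
  cross <- tcrossprod(z)

  nb <- length(distance_bins) - 1L
  out <- data.frame(from_km = distance_bins[-(nb + 1L)],
                    to_km = distance_bins[-1L],
                    moran_i = NA_real_, expected_i = -1 / (n - 1),
                    p_value = NA_real_, n_pairs = NA_integer_)
  perms <- lapply(seq_len(n_perm), function(i) sample.int(n))
  for (b in seq_len(nb)) {
    w <- d_km > out$from_km[b] & d_km <= out$to_km[b]
    diag(w) <- FALSE
    s0 <- sum(w)
    out$n_pairs[b] <- s0
    if (s0 == 0) next
    i_obs <- n / s0 * sum(cross[w]) / denom
    out$moran_i[b] <- i_obs
    i_perm <- vapply(perms, function(p) {
      zp <- z[p]
      n / s0 * sum(tcrossprod(zp)[w]) / denom
    }, numeric(1))
    out$p_value[b] <- (1 + sum(i_perm >= i_obs)) / (n_perm + 1)
  }
  sig <- !is.na(out$p_value) & out$p_value < 0.05 & out$moran_i > out$expected_i
  first_ns <- which(!sig)
  attr(out, "autocorrelation_range_km") <-
    if (length(first_ns)) out$from_km[first_ns[1]] else out$to_km[nb]
  class(out) <- c("moran_result", class(out))
  out
}

#' Moran's I residuals from a covariate-only smooth surface
#'
#' Fits a generalized additive model of carbon on the top covariates (by
#' absolute correlation with the response) with penalized spline smooths
#' and returns its residuals; the smoother is pluggable through
#' `smoother`.
#'
#' @param table Training table with `carbon` and covariate columns.
#' @param n_covariates Number of covariates to smooth over (default 5).
#' @param smoother Function `(formula, data) -> fit with residuals()`;
#'   default [mgcv::gam()].
#' @return Numeric residual vector.
#' @export
surface_residuals <- function(table, n_covariates = 5, smoother = NULL) {
  covs <- grep("^env_|^canopy$", names(table), value = TRUE)
  cors <- vapply(covs, function(v)
    abs(stats::cor(table$carbon, table[[v]])), numeric(1))
  top <- names(sort(cors, decreasing = TRUE))[seq_len(min(n_covariates, length(covs)))]
  fm <- stats::as.formula(paste("carbon ~",
    paste(sprintf("s(%s, k = 5)", top), collapse = " + ")))
  fit <- if (is.null(smoother)) mgcv::gam(fm, data = table)
         else smoother(fm, table)
  as.numeric(stats::residuals(fit))
}

#' Spatially buffered leave-one-out cross-validation
#'
#' Each observation is predicted by a model trained on all observations
#' farther than `buffer_km` away (great-circle distance), which removes
#' the optimism that spatial autocorrelation lends to random
#' cross-validation. `buffer_km = 0` reduces to classical LOO-CV.
#'
#' @param table Data frame with `lat`, `lon` and the response.
#' @param model_factory Function `train_df -> function(newdata) -> pred`.
#' @param buffer_km Buffer radius in km (>= 0).
#' @param response Name of the response column.
#' @return List with `predictions`, `observed` and `r2` (to the 1:1 line).
#' @export
buffered_loocv <- function(table, model_factory, buffer_km,
                           response = "carbon") {
  stopifnot(buffer_km >= 0, nrow(table) >= 3)
  coords <- as.matrix(table[, c("lon", "lat")])
  d_km <- geosphere::distm(coords, fun = geosphere::distHaversine) / 1000
  n <- nrow(table)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    train_idx <- which(d_km[i, ] > buffer_km)
    train_idx <- setdiff(train_idx, i)
    if (!length(train_idx))
      stop("point ", i, ": buffer excludes all training data")
    fit <- model_factory(table[train_idx, , drop = FALSE])
    pred[i] <- fit(table[i, , drop = FALSE])
  }
  obs <- table[[response]]
  list(predictions = pred, observed = obs, r2 = r2_one_to_one(obs, pred))
}

#' Random k-fold cross-validation score
#'
#' Companion to [buffered_loocv()]: the conventional (spatially naive)
#' k-fold score on the same table and model factory.
#'
#' @inheritParams buffered_loocv
#' @param k Number of folds.
#' @return List with `predictions`, `observed`, `r2`.
#' @export
kfold_cv <- function(table, model_factory, k = 10, response = "carbon") {
  n <- nrow(table)
  folds <- sample(rep_len(seq_len(k), n))
  pred <- numeric(n)
  for (f in seq_len(k)) {
    fit <- model_factory(table[folds != f, , drop = FALSE])
    pred[folds == f] <- fit(table[folds == f, , drop = FALSE])
  }
  obs <- table[[response]]
  list(predictions = pred, observed = obs, r2 = r2_one_to_one(obs, pred))
}

point_in_convex_hull <- function(px, py, hx, hy, tol = 1e-9) {
  # half-plane test around the hull (counter-clockwise); boundary counts
  # as inside (closed-hull convention)
  nh <- length(hx)
  inside <- rep(TRUE, length(px))
  for (e in seq_len(nh)) {
    x1 <- hx[e]; y1 <- hy[e]
    x2 <- hx[e %% nh + 1L]; y2 <- hy[e %% nh + 1L]
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    inside <- inside & cross >= -tol
  }
  inside
}

#' PCA convex-hull extrapolation diagnostic
#'
#' Standardizes the prediction pixels with the training means and scales,
#' projects both onto the principal components of the training
#' covariates, keeps the leading components covering at least
#' `variance_target` of the variance, builds the 2-D convex hull of the
#' training data for every component pair, and reports per pixel the
#' fraction of hulls containing it (boundary counts as inside). Pixels
#' inside at least 95% of the hulls are considered interpolated rather
#' than extrapolated.
#'
#' @param training Matrix/data frame of training covariates (>= 3 rows).
#' @param pixels Matrix/data frame of prediction covariates, same columns.
#' @param variance_target Cumulative variance threshold (default 0.90).
#' @return A `hull_diagnostic` list: `n_components`, `n_hulls`,
#'   `inside_fraction` per pixel and `share_interpolated`.
#' @export
hull_coverage <- function(training, pixels, variance_target = 0.90) {
  training <- as.matrix(training)
  pixels <- as.matrix(pixels)
  stopifnot(nrow(training) >= 3, ncol(training) == ncol(pixels))
  keep <- apply(training, 2, stats::sd) > 0
  training <- training[, keep, drop = FALSE]
  pixels <- pixels[, keep, drop = FALSE]
  pca <- stats::prcomp(training, center = TRUE, scale. = TRUE)
  cum <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
  k <- which(cum >= variance_target)[1]
  k <- max(k, 2L)
  tr <- pca$x[, seq_len(k), drop = FALSE]
  px <- scale(pixels, center = pca$center, scale = pca$scale) %*%
    pca$rotation[, seq_len(k), drop = FALSE]

  pairs <- utils::combn(k, 2)
  n_hulls <- 0L
  inside_count <- rep(0L, nrow(px))
  for (q in seq_len(ncol(pairs))) {
    a <- pairs[1, q]; b <- pairs[2, q]
    ch <- grDevices::chull(tr[, a], tr[, b])
    if (length(unique(ch)) < 3) {
      message("degenerate hull for component pair (", a, ",", b, "); skipped")
      next
    }
    ch <- rev(ch)  # chull returns clockwise; half-plane test expects CCW
    n_hulls <- n_hulls + 1L
    inside_count <- inside_count +
      point_in_convex_hull(px[, a], px[, b], tr[ch, a], tr[ch, b])
  }
  frac <- inside_count / n_hulls
  structure(list(n_components = k, n_hulls = n_hulls,
                 inside_fraction = frac,
                 share_interpolated = mean(frac >= 0.95)),
            class = "hull_diagnostic")
}

#' Partial regression of carbon on the human-disturbance gradient
#'
#' Summarizes the eight human-disturbance layers by their first principal
#' component (oriented so larger scores mean more disturbance), then
#' regresses the residuals of carbon on the environmental controls
#' against the residuals of the PC1 score on the same controls
#' (Frisch-Waugh partialling). A significantly negative slope indicates a
#' decline of carbon density along the anthropogenic degradation gradient
#' that the environmental covariates cannot explain.
#'
#' @param carbon Response vector (carbon density); internally divided by
#'   its mean so the slope is in relative-carbon units.
#' @param env Data frame/matrix of environmental controls.
#' @param human Data frame/matrix of the eight human layers.
#' @return List with `slope`, `se`, `conf_int` (95%), `p_value`, `pc1`.
#' @export
disturbance_partial_regression <- function(carbon, env, human) {
  env <- as.matrix(env)
  human <- as.matrix(human)
  n <- length(carbon)
  stopifnot(nrow(env) == n, nrow(human) == n)
  if (n <= ncol(env) + 2) stop("need more observations than controls")
  keep <- apply(env, 2, stats::sd) > 0
  env <- env[, keep, drop = FALSE]
  # drop collinear control columns
  qr_env <- qr(cbind(1, env))
  if (qr_env$rank < ncol(env) + 1) {
    used <- qr_env$pivot[seq_len(qr_env$rank)]
    used <- setdiff(used, 1L) - 1L
    message("dropping ", ncol(env) - length(used), " collinear control column(s)")
    env <- env[, used, drop = FALSE]
  }
  hsd <- apply(human, 2, stats::sd)
  pca <- stats::prcomp(human[, hsd > 0, drop = FALSE], center = TRUE,
                       scale. = TRUE)
  pc1 <- pca$x[, 1]
  orient <- sign(sum(pca$rotation[, 1]))
  if (orient == 0) orient <- 1
  pc1 <- pc1 * orient

  rel_carbon <- carbon / mean(carbon)
  r_c <- stats::residuals(stats::lm(rel_carbon ~ env))
  r_h <- stats::residuals(stats::lm(pc1 ~ env))
  fit <- stats::lm(r_c ~ r_h)
  sm <- stats::coef(summary(fit))["r_h", ]
  ci <- stats::confint(fit)["r_h", ]
  list(slope = unname(sm["Estimate"]), se = unname(sm["Std. Error"]),
       conf_int = unname(ci), p_value = unname(sm["Pr(>|t|)"]), pc1 = pc1)
}
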