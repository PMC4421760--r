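# Construct a gp_fit with fixed hyperparameters (single draw), bypassing
# MCMC; exercises the prediction path in isolation.
fixed_gp_fit <- function(coords, values, mu, sill, nugget, phi,
                         method = "euclidean") {
  D <- bhpm:::distance_matrix(coords, method = method)
  e <- eigen(exp(-phi * D), symmetric = TRUE)
  sp <- list(U = e$vectors, lam = pmax(e$values, 1e-12),
             u1 = drop(crossprod(e$vectors, rep(1, nrow(coords)))),
             uy = drop(crossprod(e$vectors, values)))
  structure(list(draws = matrix(c(mu, sill, nugget, phi), 1,
                                dimnames = list(NULL, c("mu", "sill",
                                                        "nugget", "phi"))),
                 coords = coords, values = values, phi_grid = phi,
                 spectra = list(sp), method = method, seed = 0L),
            class = "gp_fit")
}

test_that("kriging with no nugget interpolates observed sites exactly", {
  set.seed(4)
  xy <- cbind(stats::runif(20, 0, 50), stats::runif(20, 0, 50))
  locs <- planar_locs(xy)
  f <- simulate_gp_field(locs, gp_hyperparams(2, 1, 0.05, 0), seed = 8,
                         method = "euclidean")
  fit <- fixed_gp_fit(locs, f, mu = 2, sill = 1, nugget = 0, phi = 0.05)
  pred <- predict_missing(fit, locs)
  expect_equal(pred$pred_mean, unname(f), tolerance = 1e-6)
  expect_true(all(pred$pred_sd < 1e-3))

  # far beyond the decay range the prediction reverts to the field mean
  far <- planar_locs(cbind(5000, 5000), "far")
  pfar <- predict_missing(fit, far)
  expect_equal(pfar$pred_mean, 2, tolerance = 1e-6)
  expect_equal(pfar$pred_sd, 1, tolerance = 1e-6)
})

test_that("prediction matches a direct dense-matrix kriging computation", {
  set.seed(6)
  xy <- cbind(stats::runif(20, 0, 80), stats::runif(20, 0, 80))
  locs <- planar_locs(xy)
  y <- simulate_gp_field(locs, gp_hyperparams(5, 2, 0.03, 0.5), seed = 9,
                         method = "euclidean")
  mu <- 5; sill <- 2; nugget <- 0.5; phi <- 0.03
  fit <- fixed_gp_fit(locs, y, mu, sill, nugget, phi)
  new <- planar_locs(cbind(stats::runif(7, 0, 80), stats::runif(7, 0, 80)),
                     sprintf("n%d", 1:7))
  pred <- predict_missing(fit, new)

  D <- bhpm:::distance_matrix(locs, method = "euclidean")
  S <- sill * exp(-phi * D); diag(S) <- sill + nugget
  Dx <- bhpm:::distance_matrix(new, locs, method = "euclidean")
  Cx <- sill * exp(-phi * Dx)
  mean_direct <- mu + drop(Cx %*% solve(S, y - mu))
  var_direct <- sill + nugget - diag(Cx %*% solve(S, t(Cx)))
  expect_equal(pred$pred_mean, unname(mean_direct), tolerance = 1e-8)
  expect_equal(pred$pred_sd, unname(sqrt(var_direct)), tolerance = 1e-8)

  # kriging weights sum to one in the constant-mean nugget-free limit
  fit0 <- fixed_gp_fit(locs, y, mu, sill, nugget = 0, phi = phi)
  const <- predict_missing(fixed_gp_fit(locs, rep(3.7, 20), 3.7, sill, 0, phi),
                           new)
  expect_equal(const$pred_mean, rep(3.7, 7), tolerance = 1e-8)
})

test_that("hyperparameters are recovered from a field with known truth", {
  locs <- simulate_locations(180, seed = 14)
  params <- gp_hyperparams(mean = 4, sill = 1, decay = -log(0.2) / 40,
                           nugget = 0.25)
  y <- simulate_gp_field(locs, params, seed = 15)
  fit <- fit_spatial_gp(locs, unname(y), n_iter = 800, seed = 16)
  pm <- colMeans(fit$draws)
  ps <- apply(fit$draws, 2, stats::sd)
  expect_lt(abs(pm["mu"] - 4) / ps["mu"], 3.5)
  expect_lt(abs(pm["sill"] - 1) / ps["sill"], 3.5)
  expect_lt(abs(pm["nugget"] - 0.25) / ps["nugget"], 3.5)
  # same seed gives identical draws
  fit2 <- fit_spatial_gp(locs, unname(y), n_iter = 800, seed = 16)
  expect_identical(fit$draws, fit2$draws)

  # pure-nugget data: posterior mass on a small smooth-variance share
  y_iid <- simulate_gp_field(locs, gp_hyperparams(0, 0, 1, 1), seed = 17)
  fit_n <- fit_spatial_gp(locs, unname(y_iid), n_iter = 800, seed = 18)
  share <- fit_n$draws[, "sill"] /
    (fit_n$draws[, "sill"] + fit_n$draws[, "nugget"])
  expect_lt(mean(share), 0.5)
})

test_that("cross-validation separates structured from unstructured fields", {
  locs <- simulate_locations(150, seed = 24)
  # deterministic long-range trend: essentially noiseless structure
  trend <- 2 + 0.5 * locs$lon
  cv_t <- cross_validate(locs, trend + stats::rnorm(150, 0, 1e-3) * 0,
                         k = 5, seed = 25, n_iter = 300)
  expect_gt(cv_t$mean_correlation, 0.95)

  y_iid <- unname(simulate_gp_field(locs, gp_hyperparams(0, 0, 1, 1), seed = 26))
  cv_n <- cross_validate(locs, y_iid, k = 5, seed = 25, n_iter = 300)
  expect_lt(abs(cv_n$mean_correlation), 0.35)

  # metrics are invariant to relabelling the sites
  relab <- locs; relab$id <- sprintf("XX%03d", seq_len(nrow(locs)))
  cv_r <- cross_validate(relab, y_iid, k = 5, seed = 25, n_iter = 300)
  expect_equal(cv_r$folds$correlation, cv_n$folds$correlation)
  expect_equal(cv_r$mean_rmse, cv_n$mean_rmse)
})

test_that("imputation fills only missing entries and preserves provenance", {
  st <- small_study()
  cv <- st$covariates
  expect_identical(impute_all(cv, st$locations), cv)  # nothing missing

  masked <- mask_constituents(cv, 0.4, seed = 33)
  imp <- impute_all(masked, st$locations, n_iter = 300, seed = 34)
  obs <- masked$observed
  for (cn in c("ec", "ocm", "so4", "si", "no3", "na")) {
    expect_identical(imp[[cn]][obs], cv[[cn]][obs])   # observed untouched
    expect_false(anyNA(imp[[cn]]))
  }
  expect_identical(imp$observed, masked$observed)     # flags preserved
  # imputed values carry real spatial information
  expect_gt(stats::cor(imp$so4[!obs], cv$so4[!obs]), 0.3)

  all_gone <- masked; all_gone$so4 <- NA_real_
  expect_error(impute_all(all_gone, st$locations), "entirely missing")
})
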