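## Bayesian spatial Gaussian-process imputation of constituent fields.
##
## Each constituent is modelled independently as a constant-mean GP with
## exponential covariance sigma^2 exp(-phi d) + tau^2 I.  Hyperparameters
## are sampled by MCMC (conjugate mean, adaptive Metropolis on sill/nugget,
## exact griddy-Gibbs for the decay on a spectral grid); missing monitors
## are imputed by the kriging posterior predictive mean averaged over
## hyperparameter draws, with predictive SDs retained for diagnostics.

#' Priors for the spatial GP
#'
#' @param values observed field values; the inverse-gamma(2, sample
#'   variance) priors on sill and nugget are centred on the empirical
#'   variance.
#' @param corr40_range,phi_grid_size decay grid, see [bhpm_priors()].
#' @export
gp_priors <- function(values, corr40_range = c(0.01, 0.99),
                      phi_grid_size = 15) {
  v <- stats::var(values)
  list(ig_shape = 2, ig_scale = v,
       mean_center = mean(values), mean_var = 100 * max(v, 1e-12),
       phi_grid = exp(seq(log(-log(corr40_range[2]) / 40),
                          log(-log(corr40_range[1]) / 40),
                          length.out = phi_grid_size)))
}

## inverse-gamma(shape, scale) log-density up to a constant
log_invgamma <- function(x, shape, scale) -(shape + 1) * log(x) - scale / x

#' Fit a Bayesian spatial GP to observed monitor values
#'
#' @param coords data frame `id`, `lon`, `lat` of observed monitors
#'   (>= 10, distinct).
#' @param values observed concentrations, one per row of `coords`.
#' @param priors a [gp_priors()] list.
#' @param n_iter MCMC iterations (default 800).
#' @param n_burn burn-in (default half).
#' @param seed integer seed.
#' @param method distance method.
#' @return a `gp_fit` with `draws` (mu, sill, nugget, phi), the data, and
#'   the spectral cache used for prediction.
#' @export
fit_spatial_gp <- function(coords, values, priors = gp_priors(values),
                           n_iter = 800, n_burn = n_iter %/% 2, seed = 1L,
                           method = "haversine") {
  n <- nrow(coords)
  stopifnot(n >= 10, length(values) == n, n_iter > n_burn)
  D <- distance_matrix(coords, method = method)
  if (min(D[upper.tri(D)]) < 1e-6) {
    warning("near-duplicate coordinates; jitter applied")
    set.seed(derive_seed(seed, 999))
    coords$lon <- coords$lon + stats::runif(n, -1e-4, 1e-4)
    coords$lat <- coords$lat + stats::runif(n, -1e-4, 1e-4)
    D <- distance_matrix(coords, method = method)
  }
  spectra <- lapply(priors$phi_grid, function(phi) {
    e <- eigen(exp(-phi * D), symmetric = TRUE)
    list(U = e$vectors, lam = pmax(e$values, 1e-10),
         u1 = drop(crossprod(e$vectors, rep(1, n))),
         uy = drop(crossprod(e$vectors, values)))
  })

  set.seed(seed)
  mu <- mean(values)
  sill <- stats::var(values) / 2
  nugget <- stats::var(values) / 2
  gi <- ceiling(length(priors$phi_grid) / 2)
  step <- 0.4; acc <- att <- 0

  draws <- matrix(NA_real_, n_iter - n_burn, 4,
                  dimnames = list(NULL, c("mu", "sill", "nugget", "phi")))
  for (it in seq_len(n_iter)) {
    sp <- spectra[[gi]]
    d <- sill * sp$lam + nugget
    ## mean: conjugate normal (all quadratic forms via the spectral cache)
    prec <- sum(sp$u1^2 / d) + 1 / priors$mean_var
    lin <- sum(sp$u1 * sp$uy / d) + priors$mean_center / priors$mean_var
    mu <- stats::rnorm(1, lin / prec, sqrt(1 / prec))
    ur <- sp$uy - mu * sp$u1
    ## sill/nugget: joint adaptive RW Metropolis on the log scale
    lp <- function(s2, t2, dd, ur2) {
      -0.5 * sum(log(dd)) - 0.5 * sum(ur2 / dd) +
        log_invgamma(s2, priors$ig_shape, priors$ig_scale) +
        log_invgamma(t2, priors$ig_shape, priors$ig_scale) +
        log(s2) + log(t2)
    }
    ps <- sill * exp(step * stats::rnorm(1))
    pt <- nugget * exp(step * stats::rnorm(1))
    att <- att + 1
    if (log(stats::runif(1)) <
        lp(ps, pt, ps * sp$lam + pt, ur^2) - lp(sill, nugget, d, ur^2)) {
      sill <- ps; nugget <- pt; acc <- acc + 1
    }
    ## decay: exact griddy-Gibbs over the grid
    ll <- vapply(spectra, function(s) {
      dd <- sill * s$lam + nugget
      urg <- s$uy - mu * s$u1
      -0.5 * sum(log(dd)) - 0.5 * sum(urg^2 / dd)
    }, 0)
    pr <- exp(ll - max(ll))
    gi <- sample.int(length(pr), 1, prob = pr)
    if (it <= n_burn && it %% 50 == 0 && att > 0) {
      step <- step * exp(0.5 * (acc / att - 0.35))
      acc <- att <- 0
    }
    if (it > n_burn) {
      draws[it - n_burn, ] <- c(mu, sill, nugget, priors$phi_grid[gi])
    }
  }
  structure(list(draws = draws, coords = coords, values = values,
                 phi_grid = priors$phi_grid, spectra = spectra,
                 method = method, seed = seed),
            class = "gp_fit")
}

#' Kriging prediction at unobserved monitors
#'
#' For each retained hyperparameter draw, the GP conditional mean and
#' variance at the new locations; the reported imputation is the average of
#' the conditional means over draws (single-value imputation), with the
#' pooled predictive SD retained for diagnostics.
#'
#' @param fit a `gp_fit`.
#' @param new_coords data frame `id`, `lon`, `lat`.
#' @param max_draws cap on hyperparameter draws used (thinned evenly,
#'   default 100).
#' @return data frame `id`, `pred_mean`, `pred_sd`.
#' @export
predict_missing <- function(fit, new_coords, max_draws = 100) {
  m <- nrow(new_coords)
  idx <- unique(round(seq(1, nrow(fit$draws),
                          length.out = min(max_draws, nrow(fit$draws)))))
  Dx <- distance_matrix(new_coords, fit$coords, method = fit$method)  # m x n
  gidx <- match(fit$draws[, "phi"], fit$phi_grid)
  mean_acc <- matrix(0, m, length(idx))
  m2_acc <- matrix(0, m, length(idx))
  for (k in seq_along(idx)) {
    th <- fit$draws[idx[k], ]
    sp <- fit$spectra[[gidx[idx[k]]]]
    d <- th[["sill"]] * sp$lam + th[["nugget"]]
    ur <- sp$uy - th[["mu"]] * sp$u1
    siy <- sp$U %*% (ur / d)                       # Sigma^-1 (y - mu)
    Cx <- th[["sill"]] * exp(-th[["phi"]] * Dx)    # m x n cross-covariance
    mu_k <- th[["mu"]] + drop(Cx %*% siy)
    B <- crossprod(sp$U, t(Cx))                    # n x m
    var_k <- th[["sill"]] + th[["nugget"]] - colSums(B^2 / d)
    mean_acc[, k] <- mu_k
    m2_acc[, k] <- pmax(var_k, 0) + mu_k^2
  }
  pm <- rowMeans(mean_acc)
  data.frame(id = new_coords$id, pred_mean = pm,
             pred_sd = sqrt(pmax(rowMeans(m2_acc) - pm^2, 0)))
}

#' k-fold cross-validation of the GP imputation
#'
#' Random partition of the observed monitors into `k` folds; each fold is
#' held out, the GP refitted on the remainder, and the held-out values
#' predicted.  Pearson correlation and RMSE are reported per fold and
#' averaged.
#'
#' @inheritParams fit_spatial_gp
#' @param k number of folds (default 5).
#' @param ... further arguments to [fit_spatial_gp()].
#' @return list with `folds` (per-fold data frame), `mean_correlation`,
#'   `mean_rmse`, `sample_sd`, and the pooled observed/predicted pairs.
#' @export
cross_validate <- function(coords, values, k = 5, seed = 1L, ...) {
  n <- nrow(coords)
  stopifnot(k >= 2, n >= 2 * k)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  if (min(table(fold)) < 2) stop("a fold has fewer than 2 sites")
  obs_all <- pred_all <- numeric(0)
  rows <- lapply(seq_len(k), function(f) {
    tr <- fold != f
    fit <- fit_spatial_gp(coords[tr, , drop = FALSE], values[tr],
                          seed = derive_seed(seed, f), ...)
    pr <- predict_missing(fit, coords[!tr, , drop = FALSE])
    obs_all <<- c(obs_all, values[!tr])
    pred_all <<- c(pred_all, pr$pred_mean)
    data.frame(fold = f, n_test = sum(!tr),
               correlation = stats::cor(values[!tr], pr$pred_mean),
               rmse = sqrt(mean((values[!tr] - pr$pred_mean)^2)))
  })
  folds <- do.call(rbind, rows)
  list(folds = folds,
       mean_correlation = mean(folds$correlation),
       mean_rmse = mean(folds$rmse),
       sample_sd = stats::sd(values),
       observed = obs_all, predicted = pred_all)
}

#' Impute every missing constituent by spatial GP kriging
#'
#' Six independent GP fits, one per constituent; missing entries are filled
#' with the posterior predictive mean, observed values are never altered,
#' and the `observed` flags are preserved so measured and imputed values
#' stay distinguishable.
#'
#' @param covariates covariate data frame with NA constituents at masked
#'   locations.
#' @param coords location table matching `covariates$location_id`.
#' @param constituents columns to impute (default all six).
#' @param seed integer seed.
#' @param keep_sd attach `<constituent>_pred_sd` columns (default FALSE).
#' @param ... further arguments to [fit_spatial_gp()].
#' @return the covariates with constituents filled.
#' @export
impute_all <- function(covariates, coords, constituents = CONSTITUENTS,
                       seed = 1L, keep_sd = FALSE, ...) {
  co <- coords[match(covariates$location_id, coords$id), , drop = FALSE]
  for (k in seq_along(constituents)) {
    cn <- constituents[k]
    miss <- is.na(covariates[[cn]])
    if (!any(miss)) next
    if (all(miss)) stop("constituent entirely missing: ", cn)
    if (sum(!miss) < 10) stop("fewer than 10 observed sites for: ", cn)
    fit <- fit_spatial_gp(co[!miss, , drop = FALSE], covariates[[cn]][!miss],
                          seed = derive_seed(seed, k), ...)
    pr <- predict_missing(fit, co[miss, , drop = FALSE])
    covariates[[cn]][miss] <- pr$pred_mean
    if (keep_sd) {
      sd_col <- paste0(cn, "_pred_sd")
      covariates[[sd_col]] <- NA_real_
      covariates[[sd_col]][miss] <- pr$pred_sd
    }
  }
  covariates
}
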