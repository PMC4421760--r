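## Synthetic study generator.
##
## Generates complete synthetic studies with the statistical structure the
## hierarchical model assumes: spatially correlated constituent fields
## (exponential covariance with nugget), correlated community confounders,
## smooth previous-year exposure series, and Poisson mortality counts from
## the two-level generative model with known truth.  Defaults are calibrated
## to the scales of the motivating eastern-US monitoring study (exposure
## 13.7 +/- 2.13 ug/m3, ~14,500 persons at risk per location-month,
## constituent 40-mile spatial correlations between 0.05 and 0.21).

#' Spatial Gaussian-process hyperparameters
#'
#' Exponential covariance: cov(a, b) = sill * exp(-decay * d(a, b)) plus
#' `nugget` on the diagonal.  The implied correlation at distance d is
#' `sill * exp(-decay * d) / (sill + nugget)`.
#'
#' @param mean field mean (ug/m3 for constituent fields).
#' @param sill partial variance of the smooth spatial component.
#' @param decay exponential decay rate, 1/miles.
#' @param nugget micro-scale/measurement variance.
#' @return a `gp_hyperparams` list.
#' @export
gp_hyperparams <- function(mean, sill, decay, nugget) {
  stopifnot(sill >= 0, nugget >= 0, decay > 0)
  structure(list(mean = mean, sill = sill, decay = decay, nugget = nugget),
            class = "gp_hyperparams")
}

#' Calibrate GP hyperparameters from a marginal SD and a 40-mile correlation
#'
#' Splits the marginal variance `sd^2` into a smooth fraction
#' (`smooth_frac`, the sill) and a nugget, then chooses the decay so the
#' implied correlation at 40 miles equals `corr40`.
#'
#' @param mean field mean.
#' @param sd marginal SD of the field.
#' @param corr40 target correlation at 40 miles (must be < `smooth_frac`).
#' @param smooth_frac fraction of variance in the smooth component.  The
#'   default 0.85 reflects the high short-range (5-10 km) inter-monitor
#'   correlations reported for all six constituents (0.59-0.95): most of
#'   the field variance is spatially structured, with a modest
#'   micro-scale/measurement nugget.
#' @export
gp_from_corr40 <- function(mean, sd, corr40, smooth_frac = 0.85) {
  stopifnot(corr40 > 0, corr40 < smooth_frac)
  decay <- -log(corr40 / smooth_frac) / 40
  gp_hyperparams(mean = mean, sill = smooth_frac * sd^2, decay = decay,
                 nugget = (1 - smooth_frac) * sd^2)
}

## Constituent field calibration: means/SDs from the all-sites summary
## table; 40-mile correlations 0.05 (EC), 0.20 (OCM), 0.21 (SO4), 0.19 (Si),
## 0.21 (NO3), 0.20 (Na).
default_gp_params <- function() {
  list(
    ec  = gp_from_corr40(0.68, 0.24, 0.05),
    ocm = gp_from_corr40(4.05, 0.90, 0.20),
    so4 = gp_from_corr40(4.14, 0.80, 0.21),
    si  = gp_from_corr40(0.09, 0.03, 0.19),
    no3 = gp_from_corr40(1.68, 0.85, 0.21),
    na  = gp_from_corr40(0.17, 0.07, 0.20))
}

## Community-confounder generator settings: Gaussian with the reported
## pairwise correlations (income~hs 0.62, white~hs 0.50, white~black -0.84),
## remaining pairs 0, repaired to the nearest PD correlation matrix.
default_confounder_params <- function() {
  mu <- c(income = 40305, hs = 0.79, urban = 0.86, white = 0.70, black = 0.19)
  sd <- c(income = 12461, hs = 0.08, urban = 0.23, white = 0.20, black = 0.17)
  R <- diag(5)
  dimnames(R) <- list(names(mu), names(mu))
  R["income", "hs"] <- R["hs", "income"] <- 0.62
  R["white", "hs"] <- R["hs", "white"] <- 0.50
  R["white", "black"] <- R["black", "white"] <- -0.84
  ## the three reported correlations alone make R indefinite (smallest
  ## eigenvalue -0.045); clip with a floor that keeps the repaired matrix
  ## well-conditioned rather than numerically singular
  R <- as_correlation(nearest_pd(R, eps = 0.025))
  list(mean = mu, sd = sd, corr = R)
}

#' Ground truth for a synthetic study
#'
#' Collects every generator parameter: the second-level coefficient vectors
#' (`beta` for the spatially varying intercept equation -- intercept, six
#' constituents, five confounders, total-mass control, all but the intercept
#' on the standardised scale; `gamma` for the slope equation -- intercept,
#' six constituents, five confounders), the second-level error SDs, the
#' per-constituent GP hyperparameters, exposure and population settings, and
#' the study dimensions.
#'
#' Default effect sizes place nonzero intercept-equation effects on three
#' constituents (EC, Si, NO3; 1.2-1.4% per 1-SD) and nonzero slope-equation
#' effects on two (SO4, Na), alongside modest confounder effects, mirroring
#' the structure the model is designed to detect.
#'
#' @param n_locations number of monitoring locations (default 518).
#' @param months_per_location integer range (lo, hi) of usable months per
#'   location, or a single fixed value.
#' @param beta,gamma coefficient vectors; named defaults supplied.
#' @param sigma_eps0,sigma_eps1 SDs of the second-level errors.
#' @param gp_params per-constituent `gp_hyperparams` list.
#' @param confounder_params list with `mean`, `sd`, `corr`.
#' @param exposure_mean,exposure_sd across-location distribution of the
#'   long-term exposure level (ug/m3).
#' @param exposure_ar_rho,exposure_ar_sd AR(1) month-to-month dynamics of
#'   the previous-year averages (high autocorrelation is structural:
#'   adjacent windows share 11/12 of their days).
#' @param at_risk_meanlog,at_risk_sdlog log-normal across-location
#'   distribution of the monthly population at risk.
#' @param bbox study region, lon/lat rectangle (default eastern US).
#' @param location_process,n_clusters,scatter_miles monitor placement, see
#'   [simulate_locations()].
#' @param effect_scale multiplier applied to every non-intercept
#'   coefficient; 1 is the calibrated default, larger values give the
#'   strong-signal regime used in selection experiments.
#' @param seed integer seed.
#' @return a `simulation_truth` list.
#' @export
simulation_truth <- function(n_locations = 518,
                             months_per_location = c(33L, 70L),
                             beta = NULL, gamma = NULL,
                             sigma_eps0 = 0.05, sigma_eps1 = 0.004,
                             gp_params = default_gp_params(),
                             confounder_params = default_confounder_params(),
                             exposure_mean = 13.7, exposure_sd = 2.13,
                             exposure_ar_rho = 0.9, exposure_ar_sd = 0.8,
                             at_risk_meanlog = 9.206, at_risk_sdlog = 0.87,
                             bbox = c(-95, -67, 25, 47),
                             location_process = "clustered",
                             n_clusters = 40, scatter_miles = 8,
                             effect_scale = 1,
                             seed = 1L) {
  if (is.null(beta)) {
    beta <- c(intercept = log(0.0045),
              ec = 0.013, ocm = 0, so4 = 0, si = 0.014, no3 = 0.012, na = 0,
              income = -0.02, hs = -0.01, urban = 0, white = 0, black = 0.02,
              xbar = 0.01)
  }
  if (is.null(gamma)) {
    gamma <- c(intercept = 0.012,
               ec = 0, ocm = 0, so4 = 0.005, si = 0, no3 = 0, na = 0.005,
               income = -0.003, hs = 0, urban = 0, white = 0, black = 0)
  }
  stopifnot(length(beta) == 13, length(gamma) == 12,
            sigma_eps0 > 0, sigma_eps1 > 0)
  beta[-1] <- beta[-1] * effect_scale
  gamma[-1] <- gamma[-1] * effect_scale
  if (length(months_per_location) == 1) {
    months_per_location <- rep(months_per_location, 2)
  }
  structure(list(
    n_locations = as.integer(n_locations),
    months_per_location = as.integer(months_per_location),
    beta = beta, gamma = gamma,
    sigma_eps0 = sigma_eps0, sigma_eps1 = sigma_eps1,
    gp_params = gp_params, confounder_params = confounder_params,
    exposure_mean = exposure_mean, exposure_sd = exposure_sd,
    exposure_ar_rho = exposure_ar_rho, exposure_ar_sd = exposure_ar_sd,
    at_risk_meanlog = at_risk_meanlog, at_risk_sdlog = at_risk_sdlog,
    bbox = bbox, location_process = location_process,
    n_clusters = n_clusters, scatter_miles = scatter_miles,
    seed = as.integer(seed)), class = "simulation_truth")
}

#' Draw monitor locations in a lon/lat rectangle
#'
#' With `process = "clustered"` (the default) monitors are scattered around
#' uniformly placed cluster centres -- a Thomas-style process emulating the
#' dense metropolitan clustering of real monitoring networks, where nearest
#' neighbours are typically a few miles apart.  `process = "uniform"` draws
#' independently uniform coordinates.
#'
#' @param n number of locations (>= 2).
#' @param bbox numeric vector `(lon_min, lon_max, lat_min, lat_max)`.
#' @param seed integer seed.
#' @param process `"clustered"` or `"uniform"`.
#' @param n_clusters number of cluster centres (clustered process).
#' @param scatter_miles SD of the isotropic Gaussian scatter of monitors
#'   around their centre, in miles.
#' @param centers optional data frame (`lon`, `lat`) of cluster centres to
#'   reuse, so two misaligned networks (e.g. mass and speciation monitors)
#'   can share the same metropolitan structure; overrides `n_clusters`.
#' @return data frame `id`, `lon`, `lat` with zero-padded ids (so
#'   lexicographic and numeric order agree).
#' @export
simulate_locations <- function(n, bbox = c(-95, -67, 25, 47), seed = 1L,
                               process = c("clustered", "uniform"),
                               n_clusters = 40, scatter_miles = 8,
                               centers = NULL) {
  process <- match.arg(process)
  stopifnot(n >= 2)
  if (bbox[2] <= bbox[1] || bbox[4] <= bbox[3]) stop("degenerate bbox")
  set.seed(seed)
  width <- max(3L, nchar(as.character(n)))
  if (process == "uniform") {
    lon <- stats::runif(n, bbox[1], bbox[2])
    lat <- stats::runif(n, bbox[3], bbox[4])
  } else {
    if (is.null(centers)) {
      cx <- stats::runif(n_clusters, bbox[1], bbox[2])
      cy <- stats::runif(n_clusters, bbox[3], bbox[4])
    } else {
      cx <- centers$lon; cy <- centers$lat; n_clusters <- length(cx)
    }
    k <- sample.int(n_clusters, n, replace = TRUE)
    lat <- cy[k] + stats::rnorm(n, 0, scatter_miles / 69)
    lon <- cx[k] + stats::rnorm(n, 0, scatter_miles / (69 * cos(cy[k] * pi / 180)))
    lon <- pmin(pmax(lon, bbox[1]), bbox[2])
    lat <- pmin(pmax(lat, bbox[3]), bbox[4])
    dup <- duplicated(cbind(lon, lat))  # only possible via boundary clamping
    if (any(dup)) {
      lon[dup] <- lon[dup] + stats::runif(sum(dup), 1e-4, 1e-3)
      lat[dup] <- lat[dup] + stats::runif(sum(dup), 1e-4, 1e-3)
    }
  }
  data.frame(id = sprintf(paste0("L%0", width, "d"), seq_len(n)),
             lon = lon, lat = lat)
}

#' Simulate one draw of a spatial Gaussian-process field
#'
#' Multivariate normal with mean `params$mean` and covariance
#' `sill * exp(-decay * d) + nugget * I` over the supplied locations.
#'
#' @param coords data frame `id`, `lon`, `lat`.
#' @param params a [gp_hyperparams()] object.
#' @param seed integer seed.
#' @param method distance method passed to [great_circle_distance()].
#' @return numeric vector of field values, named by location id.
#' @export
simulate_gp_field <- function(coords, params, seed = 1L,
                              method = "haversine") {
  D <- distance_matrix(coords, method = method)
  if (any(D[upper.tri(D)] == 0)) stop("distinct coordinates required")
  n <- nrow(coords)
  set.seed(seed)
  if (params$sill == 0 && params$nugget == 0) {
    return(stats::setNames(rep(params$mean, n), coords$id))
  }
  Sigma <- params$sill * exp(-params$decay * D)
  diag(Sigma) <- params$sill + params$nugget
  L <- tryCatch(chol(Sigma), error = function(e) {
    diag(Sigma) <- diag(Sigma) + 1e-8 * (params$sill + params$nugget)
    tryCatch(chol(Sigma),
             error = function(e2) stop("covariance not positive definite"))
  })
  stats::setNames(drop(params$mean + crossprod(L, stats::rnorm(n))),
                  coords$id)
}

#' Simulate a complete synthetic study
#'
#' Runs the generative model forward: monitor locations, spatially
#' correlated constituent fields, correlated community confounders,
#' AR(1) previous-year exposure series, location coefficients from the
#' second-level regressions (with the covariates standardised empirically,
#' exactly as the analysis standardises them), and Poisson death counts
#' `Y_ij ~ Poisson(N_ij * exp(alpha_i0 + alpha_i1 * x*_ij))`.
#'
#' @param truth a [simulation_truth()] object.
#' @return list with `panel` (location_id, month_index, deaths, at_risk,
#'   exposure, exposure_centered), `covariates` (raw constituent and
#'   confounder values, `xbar`, `observed` flag), `locations`, `alpha`
#'   (true location coefficients) and `truth`.
#' @export
simulate_study <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  n <- truth$n_locations
  locs <- simulate_locations(n, truth$bbox, seed = derive_seed(truth$seed, 1),
                             process = truth$location_process,
                             n_clusters = truth$n_clusters,
                             scatter_miles = truth$scatter_miles)

  z <- sapply(seq_along(truth$gp_params), function(k) {
    simulate_gp_field(locs, truth$gp_params[[k]],
                      seed = derive_seed(truth$seed, 10 + k))
  })
  colnames(z) <- names(truth$gp_params)

  cp <- truth$confounder_params
  set.seed(derive_seed(truth$seed, 2))
  wz <- matrix(stats::rnorm(n * 5), n, 5) %*% chol(cp$corr)
  w <- sweep(sweep(wz, 2, cp$sd[colnames(cp$corr)], "*"),
             2, cp$mean[colnames(cp$corr)], "+")
  colnames(w) <- colnames(cp$corr)

  ## exposure: location long-term level + AR(1) monthly deviations
  set.seed(derive_seed(truth$seed, 3))
  n_i <- truth$months_per_location[1] +
    sample.int(diff(truth$months_per_location) + 1L, n, replace = TRUE) - 1L
  loc_level <- stats::rnorm(n, truth$exposure_mean, truth$exposure_sd)
  rho <- truth$exposure_ar_rho
  innov_sd <- truth$exposure_ar_sd * sqrt(1 - rho^2)
  exposure <- lapply(seq_len(n), function(i) {
    e <- numeric(n_i[i])
    e[1] <- stats::rnorm(1, 0, truth$exposure_ar_sd)
    if (n_i[i] > 1) {
      for (j in 2:n_i[i]) e[j] <- rho * e[j - 1] + stats::rnorm(1, 0, innov_sd)
    }
    pmax(loc_level[i] + e, 0.1)
  })

  covariates <- data.frame(location_id = locs$id, z, w,
                           xbar = vapply(exposure, mean, 0),
                           observed = TRUE, check.names = FALSE)

  ## location coefficients from the second level, on the standardised scale
  std <- standardize_covariates(covariates)$covariates
  Xz <- as.matrix(std[CONSTITUENTS])
  Xw <- as.matrix(std[CONFOUNDERS])
  set.seed(derive_seed(truth$seed, 4))
  alpha0 <- truth$beta[["intercept"]] +
    Xz %*% truth$beta[CONSTITUENTS] + Xw %*% truth$beta[CONFOUNDERS] +
    truth$beta[["xbar"]] * std$xbar + stats::rnorm(n, 0, truth$sigma_eps0)
  alpha1 <- truth$gamma[["intercept"]] +
    Xz %*% truth$gamma[CONSTITUENTS] + Xw %*% truth$gamma[CONFOUNDERS] +
    stats::rnorm(n, 0, truth$sigma_eps1)
  alpha0 <- drop(alpha0); alpha1 <- drop(alpha1)

  set.seed(derive_seed(truth$seed, 5))
  at_risk <- round(stats::rlnorm(n, truth$at_risk_meanlog,
                                 truth$at_risk_sdlog)) + 100
  panel <- do.call(rbind, lapply(seq_len(n), function(i) {
    xc <- exposure[[i]] - mean(exposure[[i]])
    lam <- at_risk[i] * exp(alpha0[i] + alpha1[i] * xc)
    if (any(!is.finite(lam)) || any(lam > 1e9)) {
      stop("Poisson rate overflow; use smaller coefficients")
    }
    data.frame(location_id = locs$id[i], month_index = seq_len(n_i[i]),
               deaths = stats::rpois(n_i[i], lam), at_risk = at_risk[i],
               exposure = exposure[[i]], exposure_centered = xc)
  }))
  row.names(panel) <- NULL

  list(panel = panel, covariates = covariates, locations = locs,
       alpha = data.frame(location_id = locs$id,
                          alpha0 = alpha0, alpha1 = alpha1),
       truth = truth)
}

#' Mask constituent values at a random subset of locations
#'
#' Clears the `observed` flag and sets the six constituent columns to NA at
#' exactly `round(fraction * n)` locations, emulating the misalignment of
#' mass and speciation monitor networks.
#'
#' @param covariates covariate data frame from [simulate_study()].
#' @param fraction fraction of locations to mask, in [0, 1).
#' @param seed integer seed (mask reproducible).
#' @return the covariates with masked rows NA'd and flags cleared.
#' @export
mask_constituents <- function(covariates, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction < 1)
  n_mask <- round(fraction * nrow(covariates))
  if (n_mask == 0) return(covariates)
  set.seed(seed)
  idx <- sample(nrow(covariates), n_mask)
  covariates[idx, CONSTITUENTS] <- NA_real_
  covariates$observed[idx] <- FALSE
  covariates
}
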