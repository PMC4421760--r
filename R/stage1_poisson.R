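## Stage 1: per-location Poisson regression of monthly deaths on centered
## previous-year exposure with a log population offset.  The maximum
## likelihood estimates (alpha0_hat, alpha1_hat) and their sampling
## covariance feed the second-level Bayesian regression, which treats that
## covariance as known.

#' Poisson log-likelihood for one location
#'
#' `sum_j [ Y_j (log N_j + a0 + a1 x*_j) - N_j exp(a0 + a1 x*_j) - log Y_j! ]`
#'
#' @param alpha0 log baseline mortality rate.
#' @param alpha1 log rate-ratio per ug/m3 of centered exposure.
#' @param records panel rows for a single location, with columns `deaths`,
#'   `at_risk`, `exposure_centered`.
#' @return log-likelihood value.
#' @export
poisson_loglik <- function(alpha0, alpha1, records) {
  eta <- log(records$at_risk) + alpha0 + alpha1 * records$exposure_centered
  sum(records$deaths * eta - exp(eta) - lgamma(records$deaths + 1))
}

#' Fit the stage-1 model at one location
#'
#' Maximum likelihood by iteratively reweighted least squares, with the
#' inverse observed information as the sampling covariance.  Locations with
#' zero total deaths have an intercept diverging to -Inf and are returned
#' with `converged = FALSE` so the batch fitter can exclude them.
#'
#' @param records panel rows for one location (>= 2 months, centered
#'   exposure not all equal).
#' @param location_id optional id recorded in the result (taken from the
#'   records otherwise).
#' @return a one-row data frame: `location_id`, `alpha0_hat`, `alpha1_hat`,
#'   `var00`, `var01`, `var11`, `n_months`, `converged`.
#' @export
fit_location <- function(records, location_id = NULL) {
  location_id <- location_id %||% as.character(records$location_id[1])
  n <- nrow(records)
  if (n < 2) stop("need at least 2 months per location")
  if (stats::sd(records$exposure_centered) == 0) {
    stop("centered exposure constant; slope unidentifiable")
  }
  if (sum(records$deaths) == 0) {
    return(data.frame(location_id = location_id, alpha0_hat = NA_real_,
                      alpha1_hat = NA_real_, var00 = NA_real_,
                      var01 = NA_real_, var11 = NA_real_,
                      n_months = n, converged = FALSE))
  }
  X <- cbind(1, records$exposure_centered)
  fit <- suppressWarnings(
    stats::glm.fit(X, records$deaths, family = stats::poisson(),
                   offset = log(records$at_risk)))
  ## observed information = X' W X at the MLE (canonical link)
  w <- fit$fitted.values
  info <- crossprod(X, X * w)
  vc <- solve(info)
  data.frame(location_id = location_id,
             alpha0_hat = fit$coefficients[1],
             alpha1_hat = fit$coefficients[2],
             var00 = vc[1, 1], var01 = vc[1, 2], var11 = vc[2, 2],
             n_months = n, converged = fit$converged,
             row.names = NULL)
}

#' Fit the stage-1 model at every location
#'
#' @param panel centered panel (see [center_within_location()]).
#' @param min_months locations with fewer usable months are flagged
#'   unconverged and excluded downstream (default 6).
#' @return data frame of [fit_location()] rows, ordered by `location_id`.
#' @export
fit_all_locations <- function(panel, min_months = 6) {
  ids <- sort(unique(as.character(panel$location_id)))
  out <- do.call(rbind, lapply(ids, function(id) {
    rec <- panel[panel$location_id == id, , drop = FALSE]
    if (nrow(rec) < min_months) {
      return(data.frame(location_id = id, alpha0_hat = NA_real_,
                        alpha1_hat = NA_real_, var00 = NA_real_,
                        var01 = NA_real_, var11 = NA_real_,
                        n_months = nrow(rec), converged = FALSE))
    }
    fit_location(rec, location_id = id)
  }))
  row.names(out) <- NULL
  n_bad <- sum(!out$converged)
  if (n_bad > 0) {
    warning(n_bad, " location(s) degenerate or unconverged; ",
            "excluded from the second stage")
  }
  out
}

#' Score (gradient) of the stage-1 log-likelihood
#'
#' Used to verify first-order conditions at returned estimates.
#'
#' @inheritParams poisson_loglik
#' @return length-2 gradient vector.
#' @export
poisson_score <- function(alpha0, alpha1, records) {
  mu <- exp(log(records$at_risk) + alpha0 + alpha1 * records$exposure_centered)
  r <- records$deaths - mu
  c(sum(r), sum(r * records$exposure_centered))
}
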