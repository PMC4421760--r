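## Construction of the monthly multi-site panel: previous-year exposure
## windows, within-location centering, and covariate standardisation.

#' Previous 1-year average exposure at month starts
#'
#' For each month start, the mean of the daily values in the 365-day window
#' ending the day before.  A month is emitted only when the fraction of days
#' with a value in that window is at least `min_coverage`; otherwise it is
#' dropped, which is what makes the number of usable months vary by
#' location.
#'
#' @param daily data frame with columns `date` (Date or ISO-8601 string)
#'   and `value`; one value per day, sorted or not.
#' @param month_starts vector of month-start dates at which to evaluate the
#'   window.
#' @param min_coverage minimum fraction of the 365 window days that must be
#'   observed (default 0.5).
#' @return data frame `month`, `exposure`, `n_days` (one row per retained
#'   month).
#' @export
previous_year_average <- function(daily, month_starts, min_coverage = 0.5) {
  dates <- as.Date(daily$date)
  if (anyDuplicated(dates)) stop("duplicate dates in daily series")
  o <- order(dates)
  dates <- dates[o]
  values <- daily$value[o]
  month_starts <- as.Date(month_starts)
  out <- lapply(month_starts, function(m0) {
    in_win <- dates >= (m0 - 365L) & dates <= (m0 - 1L)
    n <- sum(in_win)
    if (n / 365 < min_coverage) return(NULL)
    data.frame(month = m0, exposure = mean(values[in_win]), n_days = n)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(month = as.Date(character()), exposure = numeric(),
                      n_days = integer())
  }
  out
}

#' Center exposure within each location
#'
#' Subtracts the location-specific mean exposure, giving the within-location
#' deviations whose coefficient is the spatially varying slope; the means
#' themselves re-enter the second level as the total-mass control.
#'
#' @param panel data frame with columns `location_id`, `exposure` (and
#'   typically `month_index`, `deaths`, `at_risk`).
#' @return list with `panel` (input plus `exposure_centered`) and `xbar`
#'   (data frame `location_id`, `xbar` of per-location means).
#' @export
center_within_location <- function(panel) {
  stopifnot(all(c("location_id", "exposure") %in% names(panel)))
  counts <- table(panel$location_id)
  if (any(counts < 2)) {
    stop("locations with a single record: ",
         paste(names(counts)[counts < 2], collapse = ", "),
         " (slope unidentifiable)")
  }
  mu <- tapply(panel$exposure, panel$location_id, mean)
  panel$exposure_centered <-
    panel$exposure - as.vector(mu[as.character(panel$location_id)])
  list(panel = panel,
       xbar = data.frame(location_id = names(mu), xbar = as.numeric(mu),
                         row.names = NULL))
}

#' Standardise site-level covariates to mean 0, SD 1
#'
#' Centers and scales the named columns across locations (SD with n-1
#' denominator), so second-level coefficients read as effects per 1-SD
#' increase.  The centering/scaling constants are returned for
#' back-transformation and for applying the identical transform to new data.
#'
#' @param covariates data frame with one row per location.
#' @param columns character vector of columns to standardise (default: the
#'   six constituents, the five community confounders and `xbar` when
#'   present).
#' @param constants optional result of a previous call whose constants are
#'   reapplied instead of being recomputed.
#' @return list with `covariates` (standardised copy), `center`, `scale`
#'   (named vectors).
#' @export
standardize_covariates <- function(covariates, columns = NULL,
                                   constants = NULL) {
  if (is.null(columns)) {
    columns <- intersect(c(CONSTITUENTS, CONFOUNDERS, "xbar"),
                         names(covariates))
  }
  stopifnot(length(columns) > 0, nrow(covariates) >= 2)
  if (is.null(constants)) {
    center <- vapply(covariates[columns], function(v) mean(v, na.rm = TRUE), 0)
    scale <- vapply(covariates[columns], function(v) stats::sd(v, na.rm = TRUE), 0)
    if (any(scale == 0 | !is.finite(scale))) {
      stop("constant column(s): ",
           paste(columns[scale == 0 | !is.finite(scale)], collapse = ", "))
    }
  } else {
    center <- constants$center[columns]
    scale <- constants$scale[columns]
  }
  for (cn in columns) {
    covariates[[cn]] <- (covariates[[cn]] - center[[cn]]) / scale[[cn]]
  }
  list(covariates = covariates, center = center, scale = scale)
}

#' Undo covariate standardisation
#'
#' @param covariates standardised data frame.
#' @param constants list with `center` and `scale` from
#'   [standardize_covariates()].
#' @return data frame on the original scale.
#' @export
destandardize_covariates <- function(covariates, constants) {
  for (cn in names(constants$center)) {
    if (cn %in% names(covariates)) {
      covariates[[cn]] <- covariates[[cn]] * constants$scale[[cn]] +
        constants$center[[cn]]
    }
  }
  covariates
}
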