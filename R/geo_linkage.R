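## Linkage of misaligned monitor networks and buffer aggregation.
##
## PM2.5 mass monitors and constituent (speciation) monitors are distinct
## networks; constituent concentrations are carried over to a mass monitor
## only when a speciation monitor lies within a fixed radius (6 miles in the
## motivating study).  Deaths, population at risk and community covariates
## live at ZIP-code centroids and are aggregated over the same buffer.

EARTH_RADIUS_MILES <- 3958.8

#' Great-circle distance between monitor locations
#'
#' Haversine distance on a sphere of radius 3958.8 miles.  With
#' `method = "euclidean"` the coordinates are instead interpreted as planar
#' miles, which gives hand-computable geometry for unit testing.
#'
#' @param lon1,lat1 coordinates of the first point(s), decimal degrees
#'   (or planar miles for `method = "euclidean"`).  Vectorised.
#' @param lon2,lat2 coordinates of the second point(s).
#' @param method `"haversine"` (default) or `"euclidean"`.
#' @return distance(s) in miles.
#' @examples
#' great_circle_distance(0, 0, 1, 0)  # ~69.09 miles along the equator
#' @export
great_circle_distance <- function(lon1, lat1, lon2, lat2,
                                  method = c("haversine", "euclidean")) {
  method <- match.arg(method)
  if (method == "euclidean") {
    return(sqrt((lon1 - lon2)^2 + (lat1 - lat2)^2))
  }
  if (any(abs(c(lon1, lon2)) > 180) || any(abs(c(lat1, lat2)) > 90)) {
    stop("coordinates out of range: need lon in [-180, 180], lat in [-90, 90]")
  }
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad / 2
  dlon <- (lon2 - lon1) * rad / 2
  a <- sin(dlat)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon)^2
  a <- pmin(a, 1)
  2 * EARTH_RADIUS_MILES * asin(sqrt(a))
}

## All-pairs distance matrix between two location tables (id, lon, lat).
distance_matrix <- function(a, b = a, method = "haversine") {
  n <- nrow(a); m <- nrow(b)
  out <- matrix(
    great_circle_distance(rep(a$lon, times = m), rep(a$lat, times = m),
                          rep(b$lon, each = n), rep(b$lat, each = n),
                          method = method),
    nrow = n, ncol = m, dimnames = list(a$id, b$id))
  out
}

## Validate a monitor-location table: id unique, coordinates in range.
check_locations <- function(x, planar = FALSE) {
  stopifnot(is.data.frame(x), all(c("id", "lon", "lat") %in% names(x)))
  if (anyDuplicated(x$id)) stop("monitor ids must be unique within a network")
  if (!planar && (any(abs(x$lon) > 180) || any(abs(x$lat) > 90))) {
    stop("coordinates out of range")
  }
  invisible(x)
}

#' Link each target monitor to its nearest source monitor within a radius
#'
#' For every target the minimum-distance source with distance strictly below
#' `radius` is retained; targets with no source in range get `NA`.  Ties in
#' distance break to the lexicographically smaller source id, so the result
#' does not depend on the ordering of the source table.
#'
#' @param targets,sources data frames with columns `id`, `lon`, `lat`.
#' @param radius linkage radius in miles (default 6, the spatial-homogeneity
#'   radius assumed for constituent concentrations).
#' @param method distance method, see [great_circle_distance()].
#' @return a data frame with one row per target: `target_id`, `source_id`
#'   (NA when unlinked) and `distance_miles`.
#' @export
link_nearest_within <- function(targets, sources, radius = 6,
                                method = "haversine") {
  stopifnot(radius > 0)
  check_locations(targets, planar = method == "euclidean")
  if (nrow(targets) == 0) {
    return(data.frame(target_id = character(), source_id = character(),
                      distance_miles = numeric()))
  }
  if (nrow(sources) == 0) {
    return(data.frame(target_id = targets$id, source_id = NA_character_,
                      distance_miles = NA_real_))
  }
  check_locations(sources, planar = method == "euclidean")
  ## order sources by id so which.min's first-match rule is the tie-break
  sources <- sources[order(sources$id), , drop = FALSE]
  D <- distance_matrix(targets, sources, method = method)
  pick <- apply(D, 1, which.min)
  dist <- D[cbind(seq_len(nrow(D)), pick)]
  linked <- dist < radius
  data.frame(
    target_id = targets$id,
    source_id = ifelse(linked, sources$id[pick], NA_character_),
    distance_miles = ifelse(linked, dist, NA_real_),
    row.names = NULL)
}

#' Aggregate point values falling inside a monitor's buffer
#'
#' Mean or sum of `points$value` over points strictly within `radius` miles
#' of the monitor.  Community covariates use the mean; death and at-risk
#' counts use the sum.
#'
#' @param monitor a one-row data frame (`id`, `lon`, `lat`) or a list with
#'   `lon` and `lat`.
#' @param points data frame with columns `lon`, `lat`, `value`.
#' @param radius buffer radius in miles.
#' @param mode `"mean"` or `"sum"`.
#' @param method distance method, see [great_circle_distance()].
#' @return a list with `value` (NA when no point qualifies), `n_points`,
#'   and `empty` flag.
#' @export
aggregate_buffer <- function(monitor, points, radius = 6,
                             mode = c("mean", "sum"), method = "haversine") {
  mode <- match.arg(mode)
  stopifnot(radius > 0)
  d <- great_circle_distance(monitor$lon, monitor$lat,
                             points$lon, points$lat, method = method)
  inside <- which(d < radius)
  if (length(inside) == 0) {
    return(list(value = NA_real_, n_points = 0L, empty = TRUE))
  }
  v <- points$value[inside]
  list(value = if (mode == "mean") mean(v) else sum(v),
       n_points = length(inside), empty = FALSE)
}

#' Buffer-aggregate point values onto every monitor of a network
#'
#' Applies [aggregate_buffer()] across a monitor table.  A point whose
#' centroid falls inside two buffers is by default counted in both
#' (`assign = "all"`, the literal aggregation rule); `assign = "nearest"`
#' instead assigns each point only to its nearest monitor.
#'
#' @inheritParams aggregate_buffer
#' @param monitors data frame of monitor locations (`id`, `lon`, `lat`).
#' @param assign `"all"` or `"nearest"`.
#' @return data frame with `id`, `value`, `n_points`, `empty`.
#' @export
aggregate_buffer_all <- function(monitors, points, radius = 6,
                                 mode = c("mean", "sum"),
                                 assign = c("all", "nearest"),
                                 method = "haversine") {
  mode <- match.arg(mode)
  assign <- match.arg(assign)
  D <- t(distance_matrix(monitors, data.frame(id = seq_len(nrow(points)),
                                              lon = points$lon,
                                              lat = points$lat),
                         method = method))  # points x monitors
  if (assign == "nearest") {
    nearest <- apply(D, 1, which.min)
    D[cbind(seq_len(nrow(D)), nearest)] -> dmin
    keep <- matrix(Inf, nrow(D), ncol(D))
    keep[cbind(seq_len(nrow(D)), nearest)] <- dmin
    D <- keep
  }
  res <- lapply(seq_len(nrow(monitors)), function(i) {
    inside <- which(D[, i] < radius)
    if (length(inside) == 0) {
      return(data.frame(value = NA_real_, n_points = 0L, empty = TRUE))
    }
    v <- points$value[inside]
    data.frame(value = if (mode == "mean") mean(v) else sum(v),
               n_points = length(inside), empty = FALSE)
  })
  cbind(data.frame(id = monitors$id), do.call(rbind, res))
}
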