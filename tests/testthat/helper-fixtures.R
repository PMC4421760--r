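# Shared fixtures, built in code at test time.

# Planar monitor table (coordinates in miles, method = "euclidean").
planar_locs <- function(xy, ids = NULL) {
  n <- nrow(xy)
  data.frame(id = ids %||% sprintf("p%02d", seq_len(n)),
             lon = xy[, 1], lat = xy[, 2])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One location's panel records with known rates.
toy_records <- function(n_months = 10, alpha0 = log(0.005), alpha1 = 0.02,
                        at_risk = 10000, seed = 1) {
  set.seed(seed)
  xc <- stats::rnorm(n_months)
  xc <- xc - mean(xc)
  lam <- at_risk * exp(alpha0 + alpha1 * xc)
  data.frame(location_id = "loc1", month_index = seq_len(n_months),
             deaths = stats::rpois(n_months, lam), at_risk = at_risk,
             exposure = 13 + xc, exposure_centered = xc)
}

# Independent 2-D grid-search maximiser of the per-location likelihood.
# Centred on the closed-form intercept-only estimate, step 1e-3.
grid_search_mle <- function(records, step = 1e-3,
                            a0_half = 0.25, a1_half = 0.5) {
  a0_c <- log(sum(records$deaths) / sum(records$at_risk))
  a0 <- seq(a0_c - a0_half, a0_c + a0_half, by = step)
  a1 <- seq(-a1_half, a1_half, by = step)
  Y <- records$deaths
  off <- log(records$at_risk)
  xc <- records$exposure_centered
  best <- c(NA, NA); best_ll <- -Inf
  for (b in a1) {
    # vectorised over the a0 grid: ll(a0) = A + Y. a0 - e^{a0} S(b)
    base <- sum(Y * (off + b * xc)) - sum(lgamma(Y + 1))
    S <- sum(records$at_risk * exp(b * xc))
    ll <- base + sum(Y) * a0 - exp(a0) * S
    j <- which.max(ll)
    if (ll[j] > best_ll) { best_ll <- ll[j]; best <- c(a0[j], b) }
  }
  best
}

# Small complete study reused by several stage-2 tests.
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr <- simulation_truth(n_locations = 120, months_per_location = 60,
                             seed = 42)
      cache <<- simulate_study(tr)
    }
    cache
  }
})
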