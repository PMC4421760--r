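## Stage 2: Bayesian regression of the spatially varying intercepts and
## slopes on constituent and community covariates.
##
## The stage-1 estimates (alpha0_hat, alpha1_hat) are modelled as noisy
## observations of the true location coefficients with *known* 2x2 sampling
## covariance, and the true coefficients follow two linear regressions
##
##   alpha_i0 = X0_i' beta  + eps_i0
##   alpha_i1 = X1_i' gamma + eps_i1
##
## with independent errors (variance sigma^2) or spatially correlated
## errors (sigma^2 exp(-phi d) + tau^2 I, exponential covariance).  A Gibbs
## sampler alternates conjugate updates of the latent coefficients and the
## regression vectors with Metropolis updates of the error SDs; the spatial
## decay is sampled by exact griddy-Gibbs over a fixed log-spaced grid with
## the correlation eigendecompositions precomputed once per grid point.

#' Candidate second-level model structure
#'
#' @param covariates which covariate block enters both second-level
#'   equations: `"none"`, `"constituents"`, `"confounders"` or `"both"`.
#' @param spatial logical; spatially correlated second-level errors.
#' @return a `model_spec` object.
#' @export
model_spec <- function(covariates = c("both", "none", "constituents",
                                      "confounders"),
                       spatial = FALSE) {
  covariates <- match.arg(covariates)
  structure(list(covariates = covariates, spatial = isTRUE(spatial)),
            class = "model_spec")
}

#' All eight candidate model structures
#'
#' Four covariate blocks crossed with independent or spatial errors.
#' @return list of eight [model_spec()] objects.
#' @export
all_model_specs <- function() {
  out <- list()
  for (cv in c("none", "constituents", "confounders", "both")) {
    for (sp in c(FALSE, TRUE)) {
      out[[length(out) + 1]] <- model_spec(cv, sp)
    }
  }
  out
}

#' @export
format.model_spec <- function(x, ...) {
  paste0(x$covariates, if (x$spatial) "+spatial" else "+iid")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", format(x), "\n"); invisible(x)
}

#' Build the second-level design matrices
#'
#' The intercept-equation design carries the selected covariate blocks plus
#' the standardised location-average exposure `xbar` (the total-mass
#' control), which never enters the slope-equation design.  With
#' `covariates = "none"` both designs reduce to a lone intercept column.
#'
#' @param covariates standardised covariate data frame (see
#'   [standardize_covariates()]); constituent columns must be complete.
#' @param spec a [model_spec()].
#' @return list with `X0` (intercept design), `X1` (slope design), `ids`.
#' @export
build_design <- function(covariates, spec) {
  zcols <- switch(spec$covariates,
                  none = character(), confounders = character(),
                  constituents = CONSTITUENTS, both = CONSTITUENTS)
  wcols <- switch(spec$covariates,
                  none = character(), constituents = character(),
                  confounders = CONFOUNDERS, both = CONFOUNDERS)
  if (length(zcols) > 0 && anyNA(covariates[zcols])) {
    stop("missing constituent values; impute first (see impute_all)")
  }
  n <- nrow(covariates)
  X0 <- cbind(intercept = rep(1, n))
  if (length(zcols)) X0 <- cbind(X0, as.matrix(covariates[zcols]))
  if (length(wcols)) X0 <- cbind(X0, as.matrix(covariates[wcols]))
  if (spec$covariates != "none") X0 <- cbind(X0, xbar = covariates$xbar)
  X1 <- X0[, setdiff(colnames(X0), "xbar"), drop = FALSE]
  rownames(X0) <- rownames(X1) <- covariates$location_id
  list(X0 = X0, X1 = X1, ids = covariates$location_id)
}

#' Prior settings for the second-level sampler
#'
#' @param coef_sd SD of the mean-zero normal prior on every regression
#'   coefficient (default 10, effectively flat on the log-rate scale).
#' @param eps_sd_scale scale of the half-normal prior on the second-level
#'   error SDs (sill SD and nugget SD alike; default 1).
#' @param corr40_range range of the 40-mile correlation spanned by the
#'   decay grid (default 0.01 to 0.99).
#' @param phi_grid_size number of log-spaced decay grid points.
#' @export
bhpm_priors <- function(coef_sd = 10, eps_sd_scale = 1,
                        corr40_range = c(0.01, 0.99), phi_grid_size = 15) {
  stopifnot(coef_sd > 0, eps_sd_scale > 0,
            corr40_range[1] > 0, corr40_range[2] < 1)
  list(coef_sd = coef_sd, eps_sd_scale = eps_sd_scale,
       phi_grid = exp(seq(log(-log(corr40_range[2]) / 40),
                          log(-log(corr40_range[1]) / 40),
                          length.out = phi_grid_size)))
}

## half-normal(0, scale) log-density up to a constant
log_halfnormal <- function(x, scale) -x^2 / (2 * scale^2)

## Gaussian log-likelihood of residuals under sigma^2 R(phi) + tau^2 I,
## given the spectral decomposition of R(phi): lam eigenvalues, u = U' r.
spectral_loglik <- function(u2, lam, sigma2, tau2) {
  d <- sigma2 * lam + tau2
  -0.5 * sum(log(d)) - 0.5 * sum(u2 / d)
}

#' Fit the second-level model by MCMC
#'
#' Gibbs sampler described in the package vignette.  Unconverged stage-1
#' locations are dropped.  Reproducible: a fixed `seed`, chain count and
#' iteration count give bit-identical draws.
#'
#' @param stage1 output of [fit_all_locations()].
#' @param designs output of [build_design()].
#' @param spec the [model_spec()] being fitted.
#' @param coords location table (`id`, `lon`, `lat`); required when
#'   `spec$spatial` or when [compute_dic()] will be called on the result of
#'   a spatial fit.
#' @param priors a [bhpm_priors()] list.
#' @param n_iter iterations per chain (default 2000).
#' @param n_burn burn-in discarded per chain (default half of `n_iter`).
#' @param n_chains number of chains (default 3).
#' @param seed integer seed.
#' @param method distance method for spatial correlation.
#' @return a `bhpm_fit` with elements `draws` (kept draws, chains stacked,
#'   column `chain` last), `summaries`, `dic`, `pD`, `psrf_max`,
#'   `converged` (max PSRF <= 1.1), plus sampler internals for DIC
#'   re-evaluation.
#' @export
run_mcmc <- function(stage1, designs, spec, coords = NULL,
                     priors = bhpm_priors(), n_iter = 2000,
                     n_burn = n_iter %/% 2, n_chains = 3, seed = 1L,
                     method = "haversine") {
  stopifnot(n_iter > n_burn, n_chains >= 1)
  keep <- stage1$converged & stage1$location_id %in% designs$ids
  s1 <- stage1[keep, , drop = FALSE]
  s1 <- s1[order(s1$location_id), , drop = FALSE]
  X0 <- designs$X0[s1$location_id, , drop = FALSE]
  X1 <- designs$X1[s1$location_id, , drop = FALSE]
  n <- nrow(s1)
  if (n < ncol(X0) + 2) stop("too few converged locations for the design")

  ## per-location sampling precision (2x2 inverse of the stage-1 vcov)
  det_v <- s1$var00 * s1$var11 - s1$var01^2
  if (any(det_v <= 0)) stop("stage-1 covariances must be positive definite")
  w00 <- s1$var11 / det_v
  w01 <- -s1$var01 / det_v
  w11 <- s1$var00 / det_v
  v00 <- s1$var00; v01 <- s1$var01; v11 <- s1$var11

  spectra <- NULL
  if (spec$spatial) {
    if (is.null(coords)) stop("coords required for spatial errors")
    co <- coords[match(s1$location_id, coords$id), , drop = FALSE]
    D <- distance_matrix(co, method = method)
    spectra <- lapply(priors$phi_grid, function(phi) {
      e <- eigen(exp(-phi * D), symmetric = TRUE)
      list(U = e$vectors, lam = pmax(e$values, 1e-10))
    })
  }

  par_names <- c(paste0("beta_", colnames(X0)),
                 paste0("gamma_", colnames(X1)),
                 "sigma_eps0", "sigma_eps1")
  if (spec$spatial) {
    par_names <- c(par_names, "tau_eps0", "tau_eps1", "phi0", "phi1")
  }
  p0 <- ncol(X0); p1 <- ncol(X1)
  prior_prec <- 1 / priors$coef_sd^2

  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    ## initialise at the least-squares fit to the stage-1 estimates
    beta <- drop(solve(crossprod(X0) + 1e-8 * diag(p0), crossprod(X0, s1$alpha0_hat)))
    gamma <- drop(solve(crossprod(X1) + 1e-8 * diag(p1), crossprod(X1, s1$alpha1_hat)))
    a0 <- s1$alpha0_hat; a1 <- s1$alpha1_hat
    sig <- c(max(stats::sd(s1$alpha0_hat - X0 %*% beta), 1e-3),
             max(stats::sd(s1$alpha1_hat - X1 %*% gamma), 1e-3))
    tau <- sig / 2
    gi <- rep(ceiling(length(priors$phi_grid) / 2), 2)  # decay grid index
    step <- c(0.3, 0.3)                                 # RW step per equation
    acc <- att <- c(0, 0)

    ## marginal log-posterior of the error SDs under independent errors,
    ## latent coefficients integrated out (closed form via the per-location
    ## 2x2 covariance sigma^2 I + V_i)
    lp_sig_iid <- function(s0, s1g, r0m, r1m) {
      c00 <- s0^2 + v00; c11 <- s1g^2 + v11
      det2 <- c00 * c11 - v01^2
      q <- (c11 * r0m^2 - 2 * v01 * r0m * r1m + c00 * r1m^2) / det2
      -0.5 * sum(log(det2)) - 0.5 * sum(q) +
        log_halfnormal(s0, priors$eps_sd_scale) +
        log_halfnormal(s1g, priors$eps_sd_scale) + log(s0) + log(s1g)
    }

    kept <- matrix(NA_real_, n_iter - n_burn, length(par_names),
                   dimnames = list(NULL, par_names))
    for (it in seq_len(n_iter)) {
      adapting <- it <= n_burn

      if (!spec$spatial) {
        ## fully collapsed sweep: the latent location coefficients are
        ## integrated out analytically, so the chain moves only over
        ## (beta, gamma, sigma) -- no funnel between latents and SDs
        c00 <- sig[1]^2 + v00; c11 <- sig[2]^2 + v11
        det2 <- c00 * c11 - v01^2
        ic00 <- c11 / det2; ic01 <- -v01 / det2; ic11 <- c00 / det2
        A <- rbind(cbind(crossprod(X0, X0 * ic00), crossprod(X0, X1 * ic01)),
                   cbind(crossprod(X1, X0 * ic01), crossprod(X1, X1 * ic11)))
        A <- A + prior_prec * diag(p0 + p1)
        b <- c(crossprod(X0, ic00 * s1$alpha0_hat + ic01 * s1$alpha1_hat),
               crossprod(X1, ic01 * s1$alpha0_hat + ic11 * s1$alpha1_hat))
        th <- rmvn_precision(A, b)
        beta <- th[seq_len(p0)]; gamma <- th[p0 + seq_len(p1)]

        r0m <- s1$alpha0_hat - drop(X0 %*% beta)
        r1m <- s1$alpha1_hat - drop(X1 %*% gamma)
        for (rep in 1:3) {
          prop0 <- sig[1] * exp(step[1] * stats::rnorm(1))
          prop1 <- sig[2] * exp(step[2] * stats::rnorm(1))
          att <- att + 1
          if (log(stats::runif(1)) < lp_sig_iid(prop0, prop1, r0m, r1m) -
                lp_sig_iid(sig[1], sig[2], r0m, r1m)) {
            sig <- c(prop0, prop1); acc <- acc + 1
          }
        }
        ## occasional long-range proposal so a near-zero SD can escape
        prop0 <- sig[1] * exp(1.5 * stats::rnorm(1))
        prop1 <- sig[2] * exp(1.5 * stats::rnorm(1))
        if (log(stats::runif(1)) < lp_sig_iid(prop0, prop1, r0m, r1m) -
              lp_sig_iid(sig[1], sig[2], r0m, r1m)) {
          sig <- c(prop0, prop1)
        }
      } else {
      for (eq in 1:2) {
        X <- if (eq == 1) X0 else X1
        coefs <- if (eq == 1) beta else gamma
        ahat_own <- if (eq == 1) s1$alpha0_hat else s1$alpha1_hat
        ahat_oth <- if (eq == 1) s1$alpha1_hat else s1$alpha0_hat
        a_oth <- if (eq == 1) a1 else a0
        w_own <- if (eq == 1) w00 else w11
        ## pseudo-observation for this equation's latent coefficients,
        ## folding in the cross term of the stage-1 precision
        m <- ahat_own + (w01 / w_own) * (ahat_oth - a_oth)
        mu_prior <- drop(X %*% coefs)

        {
          sp <- spectra[[gi[eq]]]
          dinv <- 1 / (sig[eq]^2 * sp$lam + tau[eq]^2)
          Sinv <- sp$U %*% (dinv * t(sp$U))
          Q <- Sinv; diag(Q) <- diag(Q) + w_own
          a <- rmvn_precision(Q, drop(Sinv %*% mu_prior) + w_own * m)
          A <- crossprod(X, Sinv %*% X) + prior_prec * diag(ncol(X))
          coefs <- rmvn_precision(A, crossprod(X, Sinv %*% a))
          r <- a - drop(X %*% coefs)
          ## decay: exact griddy-Gibbs over the precomputed spectral grid
          ll <- vapply(spectra, function(s) {
            spectral_loglik(drop(crossprod(s$U, r))^2, s$lam,
                            sig[eq]^2, tau[eq]^2)
          }, 0)
          pr <- exp(ll - max(ll))
          gi[eq] <- sample.int(length(pr), 1, prob = pr)
          ## sill/nugget SDs: joint RW Metropolis given the decay
          u2 <- drop(crossprod(spectra[[gi[eq]]]$U, r))^2
          lam <- spectra[[gi[eq]]]$lam
          lp <- function(s, t) spectral_loglik(u2, lam, s^2, t^2) +
            log_halfnormal(s, priors$eps_sd_scale) +
            log_halfnormal(t, priors$eps_sd_scale) + log(s) + log(t)
          for (rep in 1:3) {
            ps <- sig[eq] * exp(step[eq] * stats::rnorm(1))
            pt <- tau[eq] * exp(step[eq] * stats::rnorm(1))
            att[eq] <- att[eq] + 1
            if (log(stats::runif(1)) < lp(ps, pt) - lp(sig[eq], tau[eq])) {
              sig[eq] <- ps; tau[eq] <- pt; acc[eq] <- acc[eq] + 1
            }
          }
          ps <- sig[eq] * exp(1.5 * stats::rnorm(1))
          pt <- tau[eq] * exp(1.5 * stats::rnorm(1))
          if (log(stats::runif(1)) < lp(ps, pt) - lp(sig[eq], tau[eq])) {
            sig[eq] <- ps; tau[eq] <- pt
          }
        }
        if (eq == 1) { beta <- coefs; a0 <- a } else { gamma <- coefs; a1 <- a }
      }
      }

      ## step-size adaptation toward ~40% acceptance, frozen after burn-in
      if (adapting && it %% 50 == 0) {
        for (eq in 1:2) {
          if (att[eq] > 0) {
            rate <- acc[eq] / att[eq]
            step[eq] <- step[eq] * exp(0.5 * (rate - 0.4))
          }
        }
        acc <- att <- c(0, 0)
      }
      if (it > n_burn) {
        row <- c(beta, gamma, sig)
        if (spec$spatial) {
          row <- c(row, tau, priors$phi_grid[gi])
        }
        kept[it - n_burn, ] <- row
      }
    }
    kept
  }

  chains <- lapply(seq_len(n_chains),
                   function(k) run_chain(derive_seed(seed, 100 + k)))
  draws <- do.call(rbind, chains)
  chain_id <- rep(seq_len(n_chains), each = n_iter - n_burn)

  psrf <- if (n_chains > 1) {
    vapply(seq_len(ncol(draws)),
           function(j) gelman_rhat(lapply(chains, function(m) m[, j])), 0)
  } else rep(NA_real_, ncol(draws))
  names(psrf) <- colnames(draws)

  summaries <- data.frame(
    parameter = colnames(draws),
    mean = colMeans(draws),
    sd = apply(draws, 2, stats::sd),
    q2.5 = apply(draws, 2, stats::quantile, 0.025),
    q50 = apply(draws, 2, stats::quantile, 0.5),
    q97.5 = apply(draws, 2, stats::quantile, 0.975),
    psrf = psrf, row.names = NULL)

  fit <- structure(list(
    draws = draws, chain = chain_id, summaries = summaries, spec = spec,
    psrf_max = if (all(is.na(psrf))) NA_real_ else max(psrf, na.rm = TRUE),
    converged = if (n_chains > 1) max(psrf, na.rm = TRUE) <= 1.1 else NA,
    n_iter = n_iter, n_burn = n_burn, n_chains = n_chains, seed = seed,
    internals = list(s1 = s1, X0 = X0, X1 = X1,
                     coords = if (spec$spatial) co else NULL,
                     method = method)),
    class = "bhpm_fit")
  d <- compute_dic(fit)
  fit$dic <- d$dic; fit$pD <- d$pD
  fit
}

## split-free Gelman-Rubin potential scale reduction factor
gelman_rhat <- function(chain_list) {
  m <- length(chain_list); len <- length(chain_list[[1]])
  means <- vapply(chain_list, mean, 0)
  vars <- vapply(chain_list, stats::var, 0)
  W <- mean(vars)
  B <- len * stats::var(means)
  if (W < 1e-300) return(1)
  sqrt(((len - 1) / len * W + B / len) / W)
}

#' Deviance information criterion of a second-level fit
#'
#' `DIC = Dbar + pD` with the deviance `D(theta) = -2 log p(alpha_hat |
#' theta)` -- the normal likelihood of the stage-1 estimates with the
#' latent location coefficients integrated out -- and `pD = Dbar -
#' D(theta_bar)` at the posterior-mean plug-in.
#'
#' @param fit a `bhpm_fit`.
#' @param thin evaluate the deviance at every `thin`-th kept draw
#'   (default 1).
#' @return list with `dic`, `pD`, `Dbar`.
#' @export
compute_dic <- function(fit, thin = 1) {
  draws <- fit$draws[seq(1, nrow(fit$draws), by = thin), , drop = FALSE]
  devs <- apply(draws, 1, function(th) marginal_deviance(th, fit))
  Dbar <- mean(devs)
  ## plug-in at posterior means; positive scale parameters (error SDs,
  ## nugget SDs, decay) are averaged on the log scale, where the deviance
  ## is closer to quadratic -- an arithmetic mean of a skewed decay
  ## posterior is a poor plug-in and destabilises pD
  theta_bar <- colMeans(draws)
  scale_cols <- intersect(c("sigma_eps0", "sigma_eps1", "tau_eps0",
                            "tau_eps1", "phi0", "phi1"), colnames(draws))
  theta_bar[scale_cols] <- exp(colMeans(log(draws[, scale_cols,
                                                  drop = FALSE])))
  Dhat <- marginal_deviance(theta_bar, fit)
  pD <- Dbar - Dhat
  if (pD < 0) warning("negative pD (DIC pathology); value returned as-is")
  list(dic = Dbar + pD, pD = pD, Dbar = Dbar)
}

## -2 log p(alpha_hat | theta) with latent coefficients marginalised.
marginal_deviance <- function(theta, fit) {
  int <- fit$internals
  s1 <- int$s1; X0 <- int$X0; X1 <- int$X1
  n <- nrow(s1)
  beta <- theta[paste0("beta_", colnames(X0))]
  gamma <- theta[paste0("gamma_", colnames(X1))]
  m0 <- drop(X0 %*% beta); m1 <- drop(X1 %*% gamma)
  s0 <- theta[["sigma_eps0"]]; s1g <- theta[["sigma_eps1"]]
  if (!fit$spec$spatial) {
    c00 <- s0^2 + s1$var00
    c11 <- s1g^2 + s1$var11
    c01 <- s1$var01
    det2 <- c00 * c11 - c01^2
    r0 <- s1$alpha0_hat - m0; r1 <- s1$alpha1_hat - m1
    q <- (c11 * r0^2 - 2 * c01 * r0 * r1 + c00 * r1^2) / det2
    ll <- -n * log(2 * pi) - 0.5 * sum(log(det2)) - 0.5 * sum(q)
  } else {
    D <- distance_matrix(int$coords, method = int$method)
    S0 <- s0^2 * exp(-theta[["phi0"]] * D)
    diag(S0) <- diag(S0) + theta[["tau_eps0"]]^2
    S1 <- s1g^2 * exp(-theta[["phi1"]] * D)
    diag(S1) <- diag(S1) + theta[["tau_eps1"]]^2
    S0 <- S0 + diag(s1$var00); S1 <- S1 + diag(s1$var11)
    big <- rbind(cbind(S0, diag(s1$var01)), cbind(diag(s1$var01), S1))
    r <- c(s1$alpha0_hat - m0, s1$alpha1_hat - m1)
    U <- chol(big)
    z <- backsolve(U, r, transpose = TRUE)
    ll <- -n * log(2 * pi) - sum(log(diag(U))) - 0.5 * sum(z^2)
  }
  -2 * ll
}

#' Fit all candidate model structures and rank them by DIC
#'
#' @inheritParams run_mcmc
#' @param covariates standardised covariate data frame.
#' @param specs list of [model_spec()]s (default: all eight).
#' @param ... further arguments to [run_mcmc()] (`n_iter`, `n_chains`, ...).
#' @return data frame ranked by DIC (failed fits last, DIC `Inf`), with the
#'   winner flagged, plus the fits as an attribute `fits`.
#' @export
select_model <- function(stage1, covariates, coords = NULL,
                         specs = all_model_specs(), seed = 1L, ...) {
  fits <- vector("list", length(specs))
  rows <- lapply(seq_along(specs), function(k) {
    sp <- specs[[k]]
    f <- tryCatch(
      run_mcmc(stage1, build_design(covariates, sp), sp, coords = coords,
               seed = derive_seed(seed, k), ...),
      error = function(e) e)
    if (inherits(f, "error")) {
      return(data.frame(covariates = sp$covariates, spatial = sp$spatial,
                        dic = Inf, pD = NA_real_, failed = TRUE))
    }
    fits[[k]] <<- f
    data.frame(covariates = sp$covariates, spatial = sp$spatial,
               dic = f$dic, pD = f$pD, failed = FALSE)
  })
  tab <- do.call(rbind, rows)
  ord <- order(tab$dic)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  tab$winner <- tab$rank == 1 & !tab$failed
  row.names(tab) <- NULL
  attr(tab, "fits") <- fits[ord]
  tab
}

#' Posterior effect summaries on the percent scale
#'
#' Constituent coefficients are reported as `100 (exp(coef) - 1)`: the
#' percent change in the mortality rate per 1-SD increase (intercept
#' equation, "main effect") and the percent change in the exposure-mortality
#' association per 1-SD increase (slope equation, "modifier").
#'
#' @param fit a `bhpm_fit`.
#' @param terms covariate names to report (default: the six constituents).
#' @return data frame: `term`, `effect` (main/modifier), `estimate_pct`,
#'   `lower_pct`, `upper_pct` (95% posterior interval).
#' @export
summarize_effects <- function(fit, terms = CONSTITUENTS) {
  rows <- list()
  for (eff in c("main", "modifier")) {
    prefix <- if (eff == "main") "beta_" else "gamma_"
    for (tm in terms) {
      cn <- paste0(prefix, tm)
      if (!cn %in% colnames(fit$draws)) next
      pct <- 100 * (exp(fit$draws[, cn]) - 1)
      rows[[length(rows) + 1]] <- data.frame(
        term = tm, effect = eff,
        estimate_pct = mean(pct),
        lower_pct = unname(stats::quantile(pct, 0.025)),
        upper_pct = unname(stats::quantile(pct, 0.975)))
    }
  }
  do.call(rbind, rows)
}

#' Spatially varying slope summaries on the percent scale
#'
#' Stage-1 slopes transformed to the percent increase in the mortality rate
#' per 1 ug/m3 of previous-year exposure.
#'
#' @param stage1 output of [fit_all_locations()].
#' @return data frame `location_id`, `pct_per_ugm3`.
#' @export
slope_percent_scale <- function(stage1) {
  data.frame(location_id = stage1$location_id,
             pct_per_ugm3 = 100 * (exp(stage1$alpha1_hat) - 1))
}
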