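#' @keywords internal
"_PACKAGE"

## Small numerical helpers shared across modules.

#' Draw from a multivariate normal via Cholesky
#'
#' @param mu mean vector.
#' @param Sigma covariance matrix (positive definite).
#' @return a numeric vector of length `length(mu)`.
#' @keywords internal
rmvn_chol <- function(mu, Sigma) {
  L <- chol(Sigma)
  drop(mu + crossprod(L, stats::rnorm(length(mu))))
}

## Draw x ~ N(Q^{-1} b, Q^{-1}) given precision Q and linear term b,
## using one Cholesky of Q.
rmvn_precision <- function(Q, b) {
  U <- chol(Q)
  m <- backsolve(U, backsolve(U, b, transpose = TRUE))
  drop(m + backsolve(U, stats::rnorm(length(b))))
}

#' Project a symmetric matrix to the nearest positive-definite matrix
#'
#' Eigenvalue clipping: eigenvalues below `eps` times the largest are raised
#' to that floor and the matrix is reassembled.  Used to repair correlation
#' matrices specified entry-wise.
#'
#' @param S symmetric matrix.
#' @param eps relative eigenvalue floor.
#' @return a positive-definite matrix of the same dimension.
#' @keywords internal
nearest_pd <- function(S, eps = 1e-8) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  lam <- pmax(e$values, eps * max(e$values))
  out <- e$vectors %*% (lam * t(e$vectors))
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(S)
  out
}

## Rescale a repaired correlation-like matrix back to unit diagonal.
as_correlation <- function(S) {
  d <- sqrt(diag(S))
  S / tcrossprod(d)
}

## Deterministic child seeds: keep within 32-bit signed range.
derive_seed <- function(seed, k) {
  (as.integer(seed) + 7919L * as.integer(k)) %% 2147483646L + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Canonical covariate names used throughout the package.
CONSTITUENTS <- c("ec", "ocm", "so4", "si", "no3", "na")
CONFOUNDERS  <- c("income", "hs", "urban", "white", "black")
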