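## Graphical lasso: L1-penalized sparse inverse-covariance estimation.
## Block coordinate descent over columns (Friedman et al. style); each
## column update is a lasso problem solved by cyclic coordinate descent on
## the quadratic form. Problem sizes here are small (peaks per genomic
## window), so a plain dense implementation is appropriate.

## lasso sub-problem: minimize 1/2 b' V b - s' b + rho * |b|_1
lasso_cd <- function(V, s, rho, beta0 = NULL, tol = 1e-6, max_iter = 500L) {
  k <- length(s)
  beta <- beta0 %||% numeric(k)
  if (k == 0) return(beta)
  dV <- diag(V)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(k)) {
      old <- beta[j]
      r <- s[j] - sum(V[j, ] * beta) + dV[j] * old
      bnew <- sign(r) * max(abs(r) - rho, 0) / dV[j]
      beta[j] <- bnew
      delta <- max(delta, abs(bnew - old))
    }
    if (delta < tol) break
  }
  beta
}

#' Graphical lasso estimate of a sparse precision matrix
#'
#' Estimates the inverse covariance matrix under an L1 penalty on its
#' off-diagonal entries, by block coordinate descent. With `rho = 0` the
#' estimate equals the (possibly ridge-stabilized) inverse of `S`.
#'
#' @param S covariance (or correlation) matrix, symmetric positive
#'   semi-definite.
#' @param rho non-negative L1 penalty on off-diagonal partial covariances.
#' @param tol convergence tolerance on the estimated covariance.
#' @param max_iter maximum outer sweeps.
#' @param ridge added to the diagonal of `S` when it is singular or nearly
#'   so, to stabilize the problem.
#' @param penalize_diagonal if `TRUE`, the L1 penalty also applies to the
#'   diagonal (the estimated covariance diagonal becomes
#'   `diag(S) + rho`); the default penalizes off-diagonal entries only.
#' @return list with `w` (estimated covariance), `theta` (estimated
#'   precision), and `ridged` (logical, whether stabilization was applied).
#' @export
graphical_lasso <- function(S, rho, tol = 1e-5, max_iter = 100L,
                            ridge = 1e-4, penalize_diagonal = FALSE) {
  assert_that(isSymmetric(unname(S), tol = 1e-8), "S must be symmetric")
  assert_that(rho >= 0, "rho must be non-negative")
  k <- nrow(S)
  ridged <- FALSE
  if (min(diag(S)) < 1e-12 || kappa(S) > 1e10) {
    S <- S + diag(ridge * mean(diag(S)) + 1e-12, k)
    ridged <- TRUE
  }
  if (k == 1) {
    return(list(w = S, theta = matrix(1 / S[1, 1]), ridged = ridged))
  }
  W <- if (penalize_diagonal) S + diag(rho, k) else S
  B <- matrix(0, k, k)            # per-column lasso coefficients
  for (it in seq_len(max_iter)) {
    W_old <- W
    for (j in seq_len(k)) {
      mj <- -j
      beta <- lasso_cd(W[mj, mj, drop = FALSE], S[mj, j], rho,
                       beta0 = B[mj, j], tol = min(1e-6, tol),
                       max_iter = 1000L)
      B[mj, j] <- beta
      w12 <- W[mj, mj, drop = FALSE] %*% beta
      W[mj, j] <- w12
      W[j, mj] <- w12
    }
    if (mean(abs(W - W_old)) < tol * mean(abs(S - diag(diag(S))) + 1e-12))
      break
  }
  ## recover Theta from the final regression coefficients
  Theta <- matrix(0, k, k)
  for (j in seq_len(k)) {
    mj <- -j
    denom <- W[j, j] - sum(W[mj, j] * B[mj, j])
    Theta[j, j] <- 1 / denom
    Theta[mj, j] <- -B[mj, j] * Theta[j, j]
  }
  Theta <- (Theta + t(Theta)) / 2
  list(w = W, theta = Theta, ridged = ridged)
}

## partial correlations from a precision matrix, zero diagonal
precision_to_parcor <- function(theta) {
  d <- sqrt(abs(diag(theta)))
  pc <- -theta / tcrossprod(d)
  diag(pc) <- 0
  pc
}
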