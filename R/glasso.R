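#' Gaussian graphical lasso with EBIC model selection
#'
#' L1-penalized precision-matrix estimation by block coordinate descent
#' (each column update is a lasso regression solved by coordinate
#' descent), with the regularization path scored by the extended Bayesian
#' information criterion (EBIC). Used to estimate regularized
#' partial-correlation networks over item residuals.
#'
#' @name glasso
NULL

.soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Fit the graphical lasso at one penalty
#'
#' Maximizes `log det(Theta) - tr(S Theta) - rho * ||Theta||_1(off)` (the
#' diagonal is penalized too, as in the original estimator).
#'
#' @param S covariance or correlation matrix (p x p, symmetric).
#' @param rho penalty, `>= 0`.
#' @param maxit maximum outer sweeps.
#' @param tol convergence tolerance on the average absolute change of the
#'   estimated covariance, relative to the average off-diagonal of `S`.
#' @return List with `w` (estimated covariance), `theta` (precision),
#'   `rho`, and `iters`.
#' @export
glasso_fit <- function(S, rho, maxit = 200, tol = 1e-5) {
  p <- ncol(S)
  stopifnot(isSymmetric(unname(S)), rho >= 0)
  W <- S + diag(rho, p)
  B <- matrix(0, p, p)  # column j holds beta for block j
  off <- mean(abs(S[upper.tri(S)]))
  if (!is.finite(off) || off == 0) off <- 1
  iters <- 0L
  for (it in seq_len(maxit)) {
    W_old <- W
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      W11 <- W[idx, idx, drop = FALSE]
      s12 <- S[idx, j]
      beta <- B[idx, j]
      # lasso by coordinate descent
      for (inner in seq_len(100)) {
        delta <- 0
        for (k in seq_along(idx)) {
          r <- s12[k] - sum(W11[k, -k] * beta[-k])
          bnew <- .soft(r, rho) / W11[k, k]
          delta <- max(delta, abs(bnew - beta[k]))
          beta[k] <- bnew
        }
        if (delta < tol * off) break
      }
      B[idx, j] <- beta
      w12 <- as.numeric(W11 %*% beta)
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    iters <- it
    if (mean(abs(W - W_old)) < tol * off) break
  }
  Theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    tjj <- 1 / (W[j, j] - sum(W[idx, j] * B[idx, j]))
    Theta[j, j] <- tjj
    Theta[idx, j] <- -B[idx, j] * tjj
  }
  Theta <- (Theta + t(Theta)) / 2
  dimnames(W) <- dimnames(Theta) <- dimnames(S)
  list(w = W, theta = Theta, rho = rho, iters = iters)
}

#' Partial correlations from a precision matrix
#' @param theta precision matrix.
#' @return Symmetric matrix of partial correlations, zero diagonal.
#' @export
partial_correlations <- function(theta) {
  d <- sqrt(diag(theta))
  pc <- -theta / outer(d, d)
  diag(pc) <- 0
  pc
}

#' EBIC-selected graphical lasso over a penalty grid
#'
#' @param S correlation matrix of the variables.
#' @param n number of observations behind `S`.
#' @param gamma EBIC hyperparameter (0 = plain BIC; 0.5 default).
#' @param nlambda grid size; the grid is log-spaced from the penalty that
#'   empties the graph down to 1% of it.
#' @param lambda optional explicit penalty grid.
#' @return List with the selected `theta`, `w`, `pcor`, `lambda`,
#'   `predictability` (per-node R2-like variance explained by neighbours)
#'   and the full `path` table (lambda, edges, loglik, ebic).
#' @export
ebic_glasso <- function(S, n, gamma = 0.5, nlambda = 20, lambda = NULL) {
  p <- ncol(S)
  if (is.null(lambda)) {
    lmax <- max(abs(S[upper.tri(S)]))
    if (lmax <= 0) lmax <- 0.1
    lambda <- exp(seq(log(lmax), log(0.01 * lmax), length.out = nlambda))
  }
  best <- NULL
  path <- data.frame()
  for (rho in lambda) {
    fit <- glasso_fit(S, rho)
    th <- fit$theta
    E <- sum(abs(th[upper.tri(th)]) > 1e-8)
    ld <- determinant(th, logarithm = TRUE)
    ll <- (n / 2) * (as.numeric(ld$modulus) - sum(S * th))
    ebic <- -2 * ll + E * log(n) + 4 * gamma * E * log(p)
    path <- rbind(path, data.frame(lambda = rho, edges = E,
                                   loglik = ll, ebic = ebic))
    if (is.null(best) || ebic < best$ebic)
      best <- list(fit = fit, ebic = ebic, lambda = rho)
  }
  th <- best$fit$theta
  ev <- eigen(th, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    warning("selected precision matrix not positive definite; ",
            "increasing the penalty floor may help")
  pred <- pmax(0, 1 - 1 / diag(th))  # variables on the correlation scale
  list(theta = th, w = best$fit$w,
       pcor = partial_correlations(th),
       lambda = best$lambda, predictability = pred, path = path,
       gamma = gamma, n = n)
}
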