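# Independent brute-force oracles for the AR(1)/REML harmonic regression.
# These deliberately avoid the package's whitening shortcut: the covariance
# matrix is built densely and inverted with generic linear algebra, and the
# REML maximum is found by exhaustive grid search.

oracle_gls_ar1 <- function(y, X, rho) {
  n <- length(y)
  V <- stats::toeplitz(rho^(0:(n - 1))) / (1 - rho^2)
  Vi <- solve(V)
  XtVi <- crossprod(X, Vi)
  A <- XtVi %*% X
  beta <- solve(A, XtVi %*% y)
  r <- y - X %*% beta
  rss <- drop(crossprod(r, Vi %*% r))
  p <- ncol(X)
  sig2 <- rss / (n - p)
  reml <- -0.5 * ((n - p) * (log(2 * pi * sig2) + 1) +
                    as.numeric(determinant(V)$modulus) +
                    as.numeric(determinant(A)$modulus))
  list(beta = drop(beta), reml = reml, sigma_u = sqrt(sig2))
}

oracle_reml_grid <- function(y, X, grid = seq(-0.99, 0.99, by = 0.01)) {
  vals <- vapply(grid, function(r) oracle_gls_ar1(y, X, r)$reml, numeric(1))
  best <- which.max(vals)
  list(rho = grid[best], reml = vals[best], grid = grid, vals = vals,
       fit = oracle_gls_ar1(y, X, grid[best]))
}

withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

# Standard three-cycle time grid (307 frames, as a 2.56 s recording at
# 120 FPS spanning three cardiac cycles)
standard_timing <- function() cardiac_timing(c(0, 102, 204, 307), 0.852743)
standard_t <- function() build_time_grid(standard_timing())$t
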