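#' Design matrix for harmonic regression with spline drift
#'
#' Builds the regression design for a pixel intensity series on the
#' cycle-fraction time axis: a single intercept, a truncated linear spline
#' absorbing slow movement artifact, and `order` pairs of Fourier harmonics
#' of the cardiac fundamental.
#'
#' Columns are `[1, t, (t - k1)+, (t - k2)+, ..., cos(w t), sin(w t), ...,
#' cos(w K t), sin(w K t)]` where `(z)+ = max(z, 0)` and `w` is the
#' fundamental angular frequency. With the default `basis = "2pi"` the n-th
#' harmonic is `cos(2 pi n t)`, `sin(2 pi n t)`, so the fundamental has period
#' one cardiac cycle. `basis = "pi"` uses `cos(n pi t)`, `sin(n pi t)`
#' (fundamental period two cycles) for compatibility with the half-frequency
#' parameterization.
#'
#' Columns that are identically zero (a knot at or beyond the end of the data
#' span) or collinear with earlier columns are dropped with a warning; the
#' dropped coefficients are reported as zero by the fit.
#'
#' @param t Strictly increasing cycle-fraction times.
#' @param order Number of harmonics K (>= 1).
#' @param knots Spline knot times. Default: every integer cycle boundary
#'   strictly inside the data span (t = 1, 2 for a three-cycle recording).
#' @param basis `"2pi"` (default) or `"pi"`; see Details.
#' @return A numeric matrix with attributes `roles` (column roles:
#'   `"intercept"`, `"drift_t"`, `"drift_knot<k>"`, `"cos<n>"`, `"sin<n>"`),
#'   `dropped` (roles of removed columns), `omega`, `order`, `knots`.
#' @examples
#' X <- build_design_matrix(seq(0.01, 3, by = 0.01), order = 2)
#' colnames(X)
#' @export
build_design_matrix <- function(t, order = 2L, knots = NULL,
                                basis = c("2pi", "pi")) {
  basis <- match.arg(basis)
  if (order < 1L) stop("order must be >= 1")
  if (length(t) < 2L || any(diff(t) <= 0)) stop("t must be strictly increasing")
  if (is.null(knots)) {
    top <- max(t) - sqrt(.Machine$double.eps)
    knots <- seq_len(max(0L, floor(top)))
  }
  omega <- if (basis == "2pi") 2 * pi else pi

  cols <- list("(Intercept)" = rep(1, length(t)), t = t)
  roles <- c("intercept", "drift_t")
  for (k in knots) {
    cols[[paste0("(t-", k, ")+")]] <- pmax(t - k, 0)
    roles <- c(roles, paste0("drift_knot", k))
  }
  for (n in seq_len(order)) {
    cols[[paste0("cos", n)]] <- cos(omega * n * t)
    cols[[paste0("sin", n)]] <- sin(omega * n * t)
    roles <- c(roles, paste0("cos", n), paste0("sin", n))
  }
  X <- do.call(cbind, cols)

  keep <- apply(X, 2L, function(z) max(abs(z)) > 0)
  dropped <- roles[!keep]
  X <- X[, keep, drop = FALSE]
  roles <- roles[keep]
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- qx$pivot[-seq_len(qx$rank)]
    dropped <- c(dropped, roles[bad])
    X <- X[, -bad, drop = FALSE]
    roles <- roles[-bad]
  }
  if (length(dropped))
    warning("rank-deficient design; dropped column(s): ",
            paste(dropped, collapse = ", "))
  structure(X, roles = roles, dropped = dropped, omega = omega,
            order = as.integer(order), knots = knots, basis = basis)
}

# Exact stationary AR(1) whitening of the columns of M: first row scaled by
# sqrt(1 - rho^2), remaining rows first-differenced with weight rho. With
# cov(eps) = sigma_u^2 V, V_ij = rho^|i-j| / (1 - rho^2), the whitened errors
# are iid with variance sigma_u^2 and log|V| = -log(1 - rho^2).
ar1_whiten <- function(M, rho) {
  M <- as.matrix(M)
  n <- nrow(M)
  rbind(sqrt(1 - rho^2) * M[1L, , drop = FALSE],
        M[-1L, , drop = FALSE] - rho * M[-n, , drop = FALSE])
}

#' Restricted log-likelihood profile of the AR(1) parameter
#'
#' Evaluates the REML criterion for the harmonic regression at a candidate
#' autocorrelation `rho`: the data and design are whitened by the exact
#' stationary AR(1) transform, the regression coefficients and innovation
#' variance are profiled out at their generalized-least-squares values, and
#' the restricted log-likelihood is returned. Maximizing this profile over
#' `rho` gives the REML estimate.
#'
#' @param y Intensity series.
#' @param design Design matrix from [build_design_matrix()] (any full-rank
#'   numeric matrix is accepted).
#' @param rho Candidate AR(1) autocorrelation, `|rho| < 1`.
#' @return The restricted log-likelihood (a scalar; `Inf` if the model fits
#'   exactly).
#' @examples
#' t <- seq(0.01, 3, by = 0.01)
#' y <- 2 + cos(2 * pi * t) + rnorm(length(t), sd = 0.1)
#' X <- build_design_matrix(t, order = 1)
#' reml_profile(y, X, 0) > reml_profile(y, X, 0.9)
#' @export
reml_profile <- function(y, design, rho) {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  W <- ar1_whiten(cbind(y, design), rho)
  fit <- stats::lm.fit(W[, -1L, drop = FALSE], W[, 1L])
  n <- length(y)
  p <- fit$rank
  rss <- sum(fit$residuals^2)
  if (rss <= 0) return(Inf)
  sig2 <- rss / (n - p)
  logdet_v <- -log1p(-rho^2)
  r_diag <- diag(fit$qr$qr)[seq_len(p)]
  logdet_xtx <- 2 * sum(log(abs(r_diag)))
  -0.5 * ((n - p) * (log(2 * pi * sig2) + 1) + logdet_v + logdet_xtx)
}

# GLS solve at fixed rho; returns coefficients, rss of whitened residuals,
# rank and log|X' V^-1 X|.
gls_at_rho <- function(y, X, rho) {
  W <- ar1_whiten(cbind(y, X), rho)
  fit <- stats::lm.fit(W[, -1L, drop = FALSE], W[, 1L])
  p <- fit$rank
  list(coef = fit$coefficients,
       rss = sum(fit$residuals^2),
       rank = p,
       logdet_xtx = 2 * sum(log(abs(diag(fit$qr$qr)[seq_len(p)]))))
}

#' Fit the harmonic regression model to one pixel series
#'
#' Fits intensity = intercept + linear-spline drift + Fourier harmonics with
#' AR(1) errors. The autocorrelation `rho` is estimated by restricted maximum
#' likelihood (coarse grid over `(-0.95, 0.95)` followed by bounded
#' golden-section refinement, tolerance `tol`); regression coefficients are
#' the generalized-least-squares solution at the REML `rho`. The fitted
#' periodic component yields the harmonic regression wave amplitude (HRWa,
#' peak-to-trough range over one cycle) and the time to trough (location of
#' the minimum, in cycle fractions).
#'
#' Degenerate series (constant intensity) and exactly-fitting series (zero
#' residual) are handled without error and flagged in `status`, so mapping a
#' whole frame stack never aborts on a saturated or featureless pixel.
#'
#' @param y Intensity series (mean green-channel intensity, arbitrary units).
#' @param t Cycle-fraction times, same length as `y`.
#' @param order Number of harmonics K.
#' @param knots,basis Passed to [build_design_matrix()].
#' @param rho_bounds Search interval for `rho`.
#' @param tol Convergence tolerance of the `rho` search.
#' @return An object of class `harmonic_fit`: a list with elements `a0`
#'   (intercept, reported as the mean coefficient with the spline offset fixed
#'   at zero), `harmonics` (K x 2 matrix, columns `a` = cosine and `b` = sine
#'   coefficients), `spline` (named coefficients of `t` and each truncated
#'   term; dropped columns are zero), `rho`, `sigma_u`, `loglik_reml`,
#'   `loglik_ml`, `aic`, `hrw_amplitude`, `time_to_trough`, `status`
#'   (`"ok"`, `"exact"`, `"degenerate"`, or `"nonconvergence"`), `omega`,
#'   `order`, `n`, `df_residual`.
#' @examples
#' t <- build_time_grid(cardiac_timing(c(0, 102, 204, 307), 0.852743))$t
#' y <- 120 - 4 * cos(2 * pi * (t - 0.05)) + rnorm(length(t), sd = 0.5)
#' fit <- fit_harmonic_regression(y, t)
#' c(fit$hrw_amplitude, fit$time_to_trough)
#' @export
fit_harmonic_regression <- function(y, t, order = 2L, knots = NULL,
                                    basis = "2pi",
                                    rho_bounds = c(-0.99, 0.99), tol = 1e-6) {
  X <- build_design_matrix(t, order = order, knots = knots, basis = basis)
  fit_harmonic_design(y, X, rho_bounds = rho_bounds, tol = tol)
}

# Workhorse shared by fit_harmonic_regression() and fit_stack(): the design
# is built once per stack and reused across pixels. `grid_init`, when given,
# is a precomputed coarse-grid REML argmax (see fit_series_matrix()), so only
# the local refinement is run here.
fit_harmonic_design <- function(y, X, rho_bounds = c(-0.99, 0.99), tol = 1e-6,
                                grid_init = NULL) {
  n <- length(y)
  p <- ncol(X)
  if (n < p + 2L)
    stop("series too short: need at least ", p + 2L, " points for ", p,
         " coefficients")
  roles <- attr(X, "roles")
  omega <- attr(X, "omega")
  order <- attr(X, "order")

  ss_tot <- sum((y - mean(y))^2)
  scale2 <- max(ss_tot, n * .Machine$double.eps * max(1, mean(y)^2))

  empty_fit <- function(status) {
    out <- assemble_fit(rep(0, p), roles, omega, order,
                        rho = 0, sigma_u = 0,
                        loglik_reml = NA_real_, loglik_ml = NA_real_,
                        aic = NA_real_, n = n, df_residual = n - p,
                        dropped = attr(X, "dropped"), status = status)
    out
  }
  if (ss_tot <= n * 1e-20 * max(1, mean(y)^2)) {
    fit <- empty_fit("degenerate")
    fit$a0 <- mean(y)
    return(fit)
  }

  # harmonic content below numerical noise relative to the series scale is
  # treated as absent: a drift-only pixel must map to amplitude 0, trough NA
  finish <- function(fit) {
    if (fit$hrw_amplitude <= 1e-8 * sqrt(ss_tot / n)) {
      fit$hrw_amplitude <- 0
      fit$time_to_trough <- NA_real_
    }
    fit
  }

  ols <- gls_at_rho(y, X, 0)
  if (ols$rss / ss_tot < 1e-16) {
    # exact (noiseless) fit: likelihood unbounded, rho unidentifiable
    return(finish(assemble_fit(ols$coef, roles, omega, order,
                               rho = 0, sigma_u = 0,
                               loglik_reml = Inf, loglik_ml = Inf, aic = -Inf,
                               n = n, df_residual = n - ols$rank,
                               dropped = attr(X, "dropped"),
                               status = "exact")))
  }

  prof <- function(r) reml_profile(y, X, r)
  status <- "ok"
  if (is.null(grid_init)) {
    grid <- seq(max(rho_bounds[1L], -0.95), min(rho_bounds[2L], 0.95),
                by = 0.05)
    vals <- vapply(grid, prof, numeric(1L))
    if (!any(is.finite(vals))) {
      fit <- empty_fit("nonconvergence")
      return(fit)
    }
    best <- grid[which.max(vals)]
  } else {
    best <- grid_init
    vals <- prof(best)
  }
  lo <- max(rho_bounds[1L], best - 0.05)
  hi <- min(rho_bounds[2L], best + 0.05)
  opt <- stats::optimize(prof, interval = c(lo, hi), maximum = TRUE, tol = tol)
  rho_hat <- if (opt$objective >= max(vals, na.rm = TRUE)) opt$maximum else best
  loglik_reml <- max(opt$objective, max(vals, na.rm = TRUE))

  g <- gls_at_rho(y, X, rho_hat)
  sigma_u <- sqrt(g$rss / (n - g$rank))
  sig2_ml <- g$rss / n
  loglik_ml <- -0.5 * (n * (log(2 * pi * sig2_ml) + 1) - log1p(-rho_hat^2))
  aic <- -2 * loglik_ml + 2 * (g$rank + 2)

  finish(assemble_fit(g$coef, roles, omega, order,
                      rho = rho_hat, sigma_u = sigma_u,
                      loglik_reml = loglik_reml, loglik_ml = loglik_ml,
                      aic = aic, n = n, df_residual = n - g$rank,
                      dropped = attr(X, "dropped"), status = status))
}

assemble_fit <- function(coef, roles, omega, order, rho, sigma_u,
                         loglik_reml, loglik_ml, aic, n, df_residual,
                         dropped, status) {
  coef[is.na(coef)] <- 0
  names(coef) <- roles
  harmonics <- matrix(0, nrow = order, ncol = 2L,
                      dimnames = list(paste0("n", seq_len(order)), c("a", "b")))
  for (nn in seq_len(order)) {
    if (paste0("cos", nn) %in% roles) harmonics[nn, "a"] <- coef[[paste0("cos", nn)]]
    if (paste0("sin", nn) %in% roles) harmonics[nn, "b"] <- coef[[paste0("sin", nn)]]
  }
  spline_roles <- grep("^drift", roles, value = TRUE)
  spline <- stats::setNames(coef[spline_roles], spline_roles)
  fit <- structure(
    list(
      a0 = if ("intercept" %in% roles) unname(coef[["intercept"]]) else 0,
      harmonics = harmonics,
      spline = spline,
      rho = rho,
      sigma_u = sigma_u,
      loglik_reml = loglik_reml,
      loglik_ml = loglik_ml,
      aic = aic,
      omega = omega,
      order = order,
      n = n,
      df_residual = df_residual,
      dropped = dropped,
      status = status,
      hrw_amplitude = NA_real_,
      time_to_trough = NA_real_
    ),
    class = "harmonic_fit"
  )
  fit$hrw_amplitude <- hrw_amplitude(fit)
  fit$time_to_trough <- time_to_trough(fit)
  fit
}

# Coarse-grid REML argmax for many pixel series sharing one design and time
# grid. At each candidate rho the whitened design and its QR decomposition
# are pixel-independent, so the profile is evaluated for all columns of Y
# with one multi-RHS least-squares solve; only the local refinement remains
# per-pixel. Returns NA for degenerate or exactly-fitting columns (those
# take their own fast path in fit_harmonic_design()).
grid_rho_matrix <- function(Y, X, rho_bounds = c(-0.99, 0.99)) {
  n <- nrow(Y)
  m <- ncol(Y)
  p <- ncol(X)
  ss_tot <- colSums((Y - rep(colMeans(Y), each = n))^2)
  ols <- stats::lm.fit(X, Y)
  rss0 <- colSums(as.matrix(ols$residuals)^2)
  plain <- ss_tot <= n * 1e-20 * pmax(1, colMeans(Y)^2) |
    rss0 / pmax(ss_tot, .Machine$double.xmin) < 1e-16
  grid <- seq(max(rho_bounds[1L], -0.95), min(rho_bounds[2L], 0.95),
              by = 0.05)
  remls <- matrix(-Inf, length(grid), m)
  for (k in seq_along(grid)) {
    rho <- grid[k]
    W <- ar1_whiten(cbind(X, Y), rho)
    fit <- stats::lm.fit(W[, seq_len(p), drop = FALSE],
                         W[, -seq_len(p), drop = FALSE])
    rss <- colSums(as.matrix(fit$residuals)^2)
    logdet_xtx <- 2 * sum(log(abs(diag(fit$qr$qr)[seq_len(fit$rank)])))
    remls[k, ] <- -0.5 * ((n - fit$rank) *
                            (log(2 * pi * rss / (n - fit$rank)) + 1) -
                            log1p(-rho^2) + logdet_xtx)
  }
  best <- grid[apply(remls, 2L, which.max)]
  best[plain] <- NA_real_
  best
}

#' Construct a harmonic fit from known coefficients
#'
#' Low-level constructor, mainly useful for evaluating waveforms with known
#' harmonic content and in the synthetic-data generator.
#'
#' @param harmonics K x 2 matrix (or length-2 vector for K = 1) of cosine
#'   (`a`) and sine (`b`) coefficients.
#' @param a0 Intercept.
#' @param spline Named drift coefficients (default none).
#' @param omega Fundamental angular frequency in radians per cycle fraction.
#' @return A `harmonic_fit` object with derived amplitude and trough time.
#' @examples
#' harmonic_fit(rbind(c(1, 0), c(1, 0)))$hrw_amplitude  # 3.125
#' @export
harmonic_fit <- function(harmonics, a0 = 0, spline = numeric(0),
                         omega = 2 * pi) {
  harmonics <- matrix(as.numeric(harmonics), ncol = 2L,
                      dimnames = list(NULL, c("a", "b")))
  fit <- structure(
    list(a0 = a0, harmonics = harmonics, spline = spline, rho = 0,
         sigma_u = 0, loglik_reml = NA_real_, loglik_ml = NA_real_,
         aic = NA_real_, omega = omega, order = nrow(harmonics),
         n = NA_integer_, df_residual = NA_integer_, dropped = character(0),
         status = "manual", hrw_amplitude = NA_real_,
         time_to_trough = NA_real_),
    class = "harmonic_fit"
  )
  fit$hrw_amplitude <- hrw_amplitude(fit)
  fit$time_to_trough <- time_to_trough(fit)
  fit
}

#' @export
print.harmonic_fit <- function(x, ...) {
  cat("<harmonic_fit> order", x$order, "status:", x$status, "\n")
  cat("  a0 =", format(x$a0), " rho =", format(x$rho),
      " sigma_u =", format(x$sigma_u), "\n")
  cat("  HRWa =", format(x$hrw_amplitude),
      " time to trough =", format(x$time_to_trough), "cycles\n")
  invisible(x)
}

#' Evaluate the fitted periodic component
#'
#' The periodic (pulse) part of the fitted trend: the sum of the harmonic
#' terms only, excluding the intercept and the spline drift (which model the
#' signal mean and movement artifact, not the pulse).
#'
#' @param fit A `harmonic_fit`.
#' @param t Cycle-fraction times (vectorized).
#' @return Intensity contribution of the harmonics at `t`.
#' @examples
#' periodic_component(harmonic_fit(c(1, 0)), c(0, 0.5))  # 1, -1
#' @export
periodic_component <- function(fit, t) {
  h <- unname(fit$harmonics)
  out <- numeric(length(t))
  for (n in seq_len(nrow(h)))
    out <- out + h[n, 1L] * cos(fit$omega * n * t) +
      h[n, 2L] * sin(fit$omega * n * t)
  out
}

# Locate an extremum of the periodic component by dense grid plus bounded
# local refinement (one grid cell each side, tolerance ~1e-10 cycles).
refine_extremum <- function(fit, n_grid, minimum) {
  tt <- seq(0, 1, length.out = n_grid + 1L)[-(n_grid + 1L)]
  vals <- periodic_component(fit, tt)
  idx <- if (minimum) which.min(vals) else which.max(vals)
  f <- if (minimum) function(z) periodic_component(fit, z) else
    function(z) -periodic_component(fit, z)
  opt <- stats::optimize(f, interval = tt[idx] + c(-1, 1) / n_grid,
                         tol = 1e-10)
  val <- if (minimum) opt$objective else -opt$objective
  # keep the grid point if refinement did not improve (flat regions)
  out <- if ((minimum && vals[idx] < val) || (!minimum && vals[idx] > val)) {
    list(t = tt[idx], value = vals[idx])
  } else {
    list(t = opt$minimum %% 1, value = val)
  }
  # an extremum at the cycle boundary belongs at t = 0, not 1 - epsilon
  if (1 - out$t < 1e-7) out$t <- 0
  out
}

#' Harmonic regression wave amplitude (HRWa)
#'
#' Peak-to-trough range of the fitted periodic component over one cardiac
#' cycle, located on a dense grid with local refinement. Unaffected by the
#' intercept and spline drift coefficients.
#'
#' @param fit A `harmonic_fit`.
#' @param n_grid Grid resolution over one cycle.
#' @return Nonnegative amplitude in intensity units.
#' @examples
#' hrw_amplitude(harmonic_fit(c(1, 0)))  # 2
#' @export
hrw_amplitude <- function(fit, n_grid = 4096L) {
  if (all(fit$harmonics == 0)) return(0)
  hi <- refine_extremum(fit, n_grid, minimum = FALSE)
  lo <- refine_extremum(fit, n_grid, minimum = TRUE)
  hi$value - lo$value
}

#' Time to trough of the fitted pulse wave
#'
#' Location of the minimum ("foot") of the fitted periodic component within
#' one cardiac cycle, in cycle fractions. `t = 0` (mod 1) is the
#' oximetry-synchronized cycle boundary. Ties are broken toward the smallest
#' time; a zero-amplitude fit has no trough and returns `NA`.
#'
#' @inheritParams hrw_amplitude
#' @return Trough time in `[0, 1)`, or `NA` if the amplitude is zero.
#' @examples
#' time_to_trough(harmonic_fit(c(1, 0)))   # 0.5
#' time_to_trough(harmonic_fit(c(-1, 0)))  # 0
#' @export
time_to_trough <- function(fit, n_grid = 4096L) {
  if (all(fit$harmonics == 0)) return(NA_real_)
  refine_extremum(fit, n_grid, minimum = TRUE)$t %% 1
}

#' Select the harmonic order by AIC
#'
#' Fits the model at orders `1..max_order` and returns the order minimizing
#' the Akaike Information Criterion. The AIC is computed from the full
#' maximum-likelihood log-likelihood (profiled at the REML autocorrelation)
#' rather than the restricted likelihood, because restricted likelihoods are
#' not comparable across different fixed-effect structures; the parameter
#' count is the number of regression coefficients plus two (rho, sigma_u).
#'
#' @inheritParams fit_harmonic_regression
#' @param max_order Largest harmonic order to consider.
#' @return The selected order (integer) with attribute `aic`, the per-order
#'   AIC values.
#' @examples
#' t <- seq(1, 300) / 100
#' y <- cos(2 * pi * t) + 0.4 * cos(4 * pi * t) + rnorm(300, sd = 0.3)
#' select_order_aic(y, t, max_order = 3)
#' @export
select_order_aic <- function(y, t, max_order = 4L, knots = NULL,
                             basis = "2pi") {
  if (max_order < 1L) stop("max_order must be >= 1")
  aics <- rep(NA_real_, max_order)
  for (k in seq_len(max_order)) {
    fit <- tryCatch(
      fit_harmonic_regression(y, t, order = k, knots = knots, basis = basis),
      error = function(e) NULL
    )
    if (!is.null(fit) && fit$status %in% c("ok", "exact"))
      aics[k] <- fit$aic
  }
  if (all(is.na(aics))) stop("all candidate orders failed to fit")
  structure(which.min(aics), aic = aics)
}
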