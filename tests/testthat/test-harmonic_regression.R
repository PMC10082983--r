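test_that("design matrix has the documented structure", {
  t <- standard_t()
  X <- build_design_matrix(t, order = 2)
  expect_equal(ncol(X), 8L)  # intercept + t + 2 knots + 2x2 harmonics
  expect_equal(attr(X, "roles"),
               c("intercept", "drift_t", "drift_knot1", "drift_knot2",
                 "cos1", "sin1", "cos2", "sin2"))
  expect_equal(X[, "cos1"], cos(2 * pi * t))
  # truncation below zero: (z)+ = z for z > 0, 0 otherwise
  expect_equal(X[, "(t-1)+"], pmax(t - 1, 0))
  expect_true(all(X[t <= 1, "(t-1)+"] == 0))

  # one-cycle data: both knot columns are identically zero by the
  # truncation rule ((z)+ = 0 for z <= 0) and are dropped
  expect_warning(
    X1 <- build_design_matrix(c(0.25, 0.5, 0.75, 1), order = 1,
                              knots = c(1, 2)),
    "dropped"
  )
  expect_equal(ncol(X1), 4L)
  expect_setequal(attr(X1, "dropped"), c("drift_knot1", "drift_knot2"))
  expect_equal(attr(X1, "roles"), c("intercept", "drift_t", "cos1", "sin1"))
  # a knot with data beyond it survives
  X2 <- build_design_matrix(seq(0.1, 2, by = 0.1), order = 1, knots = 1)
  expect_true("drift_knot1" %in% attr(X2, "roles"))

  # pi basis halves the fundamental frequency
  Xp <- build_design_matrix(t, order = 1, basis = "pi")
  expect_equal(Xp[, "cos1"], cos(pi * t))
})

test_that("noiseless model data are recovered exactly", {
  t <- standard_t()
  y <- 2 + cos(2 * pi * t)
  fit <- fit_harmonic_regression(y, t, order = 2)
  expect_equal(fit$a0, 2, tolerance = 1e-8)
  expect_equal(fit$harmonics["n1", "a"], 1, tolerance = 1e-8)
  expect_lt(max(abs(c(fit$harmonics["n1", "b"], fit$harmonics["n2", ],
                      fit$spline))), 1e-8)
  expect_equal(fit$hrw_amplitude, 2, tolerance = 1e-8)
  expect_equal(fit$time_to_trough, 0.5, tolerance = 1e-6)
  expect_identical(fit$status, "exact")

  # full model, all terms active, rho fixed at 0 by construction
  y2 <- 5 + 0.7 * t - 0.9 * pmax(t - 1, 0) + 0.4 * pmax(t - 2, 0) +
    1.2 * cos(2 * pi * t) - 0.4 * sin(2 * pi * t) +
    0.3 * cos(4 * pi * t) + 0.1 * sin(4 * pi * t)
  fit2 <- fit_harmonic_regression(y2, t, order = 2)
  expect_equal(unname(fit2$spline["drift_t"]), 0.7, tolerance = 1e-8)
  expect_equal(unname(fit2$spline["drift_knot1"]), -0.9, tolerance = 1e-8)
  expect_equal(unname(fit2$harmonics["n2", "b"]), 0.1, tolerance = 1e-8)
})

test_that("constant series yields a flagged zero-amplitude fit, not an error", {
  t <- standard_t()
  fit <- fit_harmonic_regression(rep(7, length(t)), t)
  expect_identical(fit$status, "degenerate")
  expect_equal(fit$hrw_amplitude, 0)
  expect_true(is.na(fit$time_to_trough))
  expect_equal(fit$a0, 7)
})

test_that("periodic component, amplitude and trough match closed forms", {
  f_cos <- harmonic_fit(c(1, 0))
  expect_equal(periodic_component(f_cos, c(0, 0.5)), c(1, -1))
  expect_equal(periodic_component(harmonic_fit(c(0, 1)), 0.25), 1)
  f_12 <- harmonic_fit(rbind(c(1, 0), c(1, 0)))
  expect_equal(periodic_component(f_12, 0), 2)

  expect_equal(hrw_amplitude(f_cos), 2)
  expect_equal(hrw_amplitude(harmonic_fit(rbind(c(0, 0), c(0, 0)))), 0)
  # stationary point of cos(2*pi*t) + cos(4*pi*t): trough where
  # cos(2*pi*t) = -1/4, peak-to-trough 2 - (-9/8) = 3.125
  expect_equal(hrw_amplitude(f_12), 3.125, tolerance = 1e-9)
  expect_equal(time_to_trough(f_12), acos(-0.25) / (2 * pi),
               tolerance = 1e-6)

  expect_equal(time_to_trough(f_cos), 0.5, tolerance = 1e-6)
  expect_equal(time_to_trough(harmonic_fit(c(-1, 0))), 0, tolerance = 1e-6)
  expect_true(is.na(time_to_trough(harmonic_fit(c(0, 0)))))
})

test_that("amplitude and trough ignore intercept and spline coefficients", {
  h <- rbind(c(1.2, -0.4), c(0.3, 0.1))
  plain <- harmonic_fit(h)
  shifted <- harmonic_fit(h, a0 = 55,
                          spline = c(drift_t = 3, drift_knot1 = -7,
                                     drift_knot2 = 2))
  expect_identical(plain$hrw_amplitude, shifted$hrw_amplitude)
  expect_identical(plain$time_to_trough, shifted$time_to_trough)
  expect_true(plain$time_to_trough >= 0 && plain$time_to_trough < 1)
})

test_that("GLS at rho = 0 equals ordinary least squares exactly", {
  t <- standard_t()
  set.seed(3)
  y <- simulate_pixel_series(t, rbind(c(1, 0.5)), a0 = 4, rho = 0,
                             sigma_u = 0.5)
  X <- build_design_matrix(t, order = 2)
  W <- retivel:::ar1_whiten(cbind(y, X), 0)
  expect_equal(W[, 1], y)
  gls0 <- retivel:::gls_at_rho(y, X, 0)
  ols <- lm.fit(X, y)
  expect_equal(gls0$coef, ols$coefficients)
  expect_equal(gls0$rss, sum(ols$residuals^2))
})

test_that("REML profile matches the dense-covariance oracle", {
  t <- standard_t()
  X <- build_design_matrix(t, order = 2)
  set.seed(4)
  y <- simulate_pixel_series(t, rbind(c(1.2, -0.4), c(0.3, 0.1)), a0 = 5,
                             drift = c(1, -2, 1), rho = 0.5, sigma_u = 0.2)
  for (rho in c(-0.6, 0, 0.3, 0.8))
    expect_equal(reml_profile(y, X, rho), oracle_gls_ar1(y, X, rho)$reml,
                 tolerance = 1e-8)
  expect_error(reml_profile(y, X, 1), "< 1")
})

test_that("REML rho search agrees with the exhaustive grid oracle", {
  t <- standard_t()
  X <- build_design_matrix(t, order = 2)
  set.seed(5)
  for (rho_true in c(0, 0.3, 0.5, 0.8)) {
    y <- simulate_pixel_series(t, rbind(c(1.2, -0.4), c(0.3, 0.1)), a0 = 5,
                               drift = c(1, -2, 1), rho = rho_true,
                               sigma_u = 0.2)
    g <- oracle_reml_grid(y, X, grid = seq(-0.95, 0.95, by = 0.01))
    fit <- fit_harmonic_regression(y, t, order = 2)
    expect_lt(abs(fit$rho - g$rho), 0.011)
    # GLS coefficients at the oracle's argmax agree with the fit
    want <- c(fit$harmonics["n1", "a"], fit$harmonics["n1", "b"],
              fit$harmonics["n2", "a"], fit$harmonics["n2", "b"])
    expect_equal(unname(g$fit$beta[c("cos1", "sin1", "cos2", "sin2")]),
                 want, tolerance = 5e-3)
  }
})

test_that("coefficients and rho match nlme::gls with corAR1", {
  t <- standard_t()
  set.seed(9)
  y <- simulate_pixel_series(t, rbind(c(1.2, -0.4), c(0.3, 0.1)), a0 = 5,
                             rho = 0.5, sigma_u = 0.3)
  X <- build_design_matrix(t, order = 2)
  d <- as.data.frame(X[, -1])
  names(d) <- c("tt", "k1", "k2", "c1", "s1", "c2", "s2")
  d$y <- y
  gfit <- nlme::gls(y ~ tt + k1 + k2 + c1 + s1 + c2 + s2, data = d,
                    correlation = nlme::corAR1(), method = "REML")
  fit <- fit_harmonic_regression(y, t, order = 2)
  expect_equal(unname(stats::coef(gfit$modelStruct$corStruct,
                                  unconstrained = FALSE)),
               fit$rho, tolerance = 1e-4)
  expect_equal(unname(stats::coef(gfit)[c("c1", "s1", "c2", "s2")]),
               c(fit$harmonics["n1", ], fit$harmonics["n2", ]),
               tolerance = 1e-5, ignore_attr = TRUE)
  # nlme reports the marginal error SD; ours is the innovation SD
  expect_equal(gfit$sigma, fit$sigma_u / sqrt(1 - fit$rho^2),
               tolerance = 1e-4)
})

test_that("rho estimates center on the truth", {
  t <- seq_len(300) / 100
  h <- rbind(c(2, 0), c(0.6, 0.4))
  set.seed(7)
  # white-noise series: REML argmax near 0
  rhohat0 <- replicate(10, {
    y <- simulate_pixel_series(t, h, rho = 0, sigma_u = 0.5)
    fit_harmonic_regression(y, t)$rho
  })
  expect_lt(max(abs(rhohat0)), 0.15)
  # strong autocorrelation
  set.seed(8)
  rhohat8 <- replicate(10, {
    y <- simulate_pixel_series(t, h, rho = 0.8, sigma_u = 0.5)
    fit_harmonic_regression(y, t)$rho
  })
  expect_lt(abs(mean(rhohat8) - 0.8), 0.1)
})

test_that("seeded coefficient recovery stays near the truth", {
  t <- standard_t()
  truth <- c(1.2, -0.4, 0.3, 0.1)
  set.seed(21)
  est <- replicate(50, {
    y <- simulate_pixel_series(t, rbind(truth[c(1, 2)], truth[c(3, 4)]),
                               a0 = 5, drift = c(1, -2, 1), rho = 0.5,
                               sigma_u = 0.2)
    fit <- fit_harmonic_regression(y, t)
    c(fit$harmonics["n1", ], fit$harmonics["n2", ])
  })
  mae <- rowMeans(abs(est - truth))
  # innovations sd 0.2, n = 307: coefficient-scale noise is a few times
  # sigma_u / sqrt(n) ~ 0.011; allow 3x the marginal-noise bound
  expect_true(all(mae < 3 * 0.2 / sqrt(length(t)) * 3))
})

test_that("AIC order selection behaves across signal content", {
  t <- seq_len(300) / 100
  expect_identical(as.integer(select_order_aic(
    rnorm(300) + cos(2 * pi * t), t, max_order = 1)), 1L)
  # pure first harmonic at high SNR: order 1 preferred in the majority
  set.seed(12)
  sel1 <- replicate(20, {
    y <- simulate_pixel_series(t, rbind(c(2, 0)), rho = 0.3, sigma_u = 0.2)
    as.integer(select_order_aic(y, t, max_order = 3))
  })
  expect_gt(mean(sel1 == 1L), 0.5)
  # first + second harmonic content: order 2 preferred in the majority
  set.seed(11)
  sel2 <- replicate(20, {
    y <- simulate_pixel_series(t, rbind(c(2, 0), c(0.6, 0.4)), rho = 0.3,
                               sigma_u = 0.5)
    as.integer(select_order_aic(y, t, max_order = 3))
  })
  expect_gt(mean(sel2 == 2L), 0.5)
})
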