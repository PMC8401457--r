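test_that("4PL fit recovers noiseless parameters in both orientations", {
  t <- seq(0, 20, by = 0.2)
  cases <- list(c(c = 0, d = 1, b = -1, e = 10),      # increasing
                c(c = 0.2, d = 2.5, b = -0.6, e = 7), # increasing, scaled
                c(c = 0, d = 1, b = 1, e = 12))       # decreasing (b > 0)
  for (p in cases) {
    y <- f4pl(t, p["c"], p["d"], p["b"], p["e"])
    fit <- fit_logistic4(t, y)
    expect_true(fit$converged)
    expect_lt(max(abs(fit$par - p[names(fit$par)])), 1e-6)
    # parametrization identity: curve value at x = e is the midpoint
    expect_equal(predict(fit, fit$par[["e"]]),
                 (p[["c"]] + p[["d"]]) / 2, tolerance = 1e-8)
  }
  expect_error(fit_logistic4(1:4, c(1, 2, 3, 4)), "5 points")
  expect_error(fit_logistic4(1:6, rep(2, 6)), "constant")
})

test_that("4PL on (0,1)-normalized sigmoid data pins the asymptotes", {
  sim <- generate_growth_curves(synth_config(n_wells = 1, duration = 24,
                                             noise_sd = 0.01, seed = 2))
  nds <- normalize_unit(sim$dataset)
  fit <- fit_logistic4(nds$time, nds$impedance[, 1])
  expect_lt(abs(fit$par[["c"]]), 0.05)
  expect_lt(abs(fit$par[["d"]] - 1), 0.05)
})

test_that("4PL symmetry: reflecting y negates b and keeps e", {
  t <- seq(0, 20, by = 0.25)
  set.seed(5)
  y <- f4pl(t, 0, 1, -0.8, 9) + rnorm(length(t), 0, 0.005)
  up <- fit_logistic4(t, y)
  dn <- fit_logistic4(t, 1 - y)   # (c + d) - y with c = 0, d = 1
  expect_equal(up$par[["e"]], dn$par[["e"]], tolerance = 1e-4)
  expect_equal(up$par[["b"]], -dn$par[["b"]], tolerance = 1e-4)
})

test_that("segmented fit recovers exact broken-line knots and slopes", {
  tt <- seq(0, 30, by = 0.1)
  cases <- list(list(y = pmax(tt - 5, 0) * 2, psi = 5,
                     slopes = c(0, 2), npsi = 1),
                list(y = 3 + pmax(tt - 8, 0) * 1.5 - pmax(tt - 17, 0) * 1.5,
                     psi = c(8, 17), slopes = c(0, 1.5, 0), npsi = 2),
                list(y = pmax(tt - 10, 0) * 2 - pmax(tt - 20, 0) * 1 +
                       pmax(tt - 25, 0) * 1,
                     psi = c(10, 20, 25), slopes = c(0, 2, 1, 2), npsi = 3))
  for (cs in cases) {
    fit <- fit_segmented(tt, cs$y, npsi = cs$npsi)
    expect_true(fit$converged)
    expect_lt(max(abs(fit$psi - cs$psi)), 1e-3)
    expect_lt(max(abs(fit$slopes - cs$slopes)), 1e-6)
  }
  expect_error(fit_segmented(tt, tt, npsi = 0), "at least 1")
  expect_error(fit_segmented(1:7, 1:7, npsi = 2), "at least")
})

test_that("adding knots never increases the segmented RSS", {
  sim <- generate_growth_curves(synth_config(n_wells = 1, duration = 30,
                                             osc_amp = 0.05, seed = 9))
  y <- sim$dataset$impedance[, 1]
  rss <- vapply(3:7, function(np)
    fit_segmented(sim$dataset$time, y, np)$gof$rss, numeric(1))
  expect_true(all(diff(rss) <= 1e-9 * rss[-length(rss)]))
})

test_that("segmented knots agree with an independent implementation", {
  skip_if_not_installed("segmented")
  tt <- seq(0, 30, by = 0.1)
  set.seed(2)
  y <- pmax(tt - 12, 0) * 1.5 + rnorm(length(tt), 0, 0.3)
  mine <- fit_segmented(tt, y, npsi = 1)
  ref <- segmented::segmented(stats::lm(y ~ tt), seg.Z = ~tt, npsi = 1)
  expect_equal(mine$psi, unname(ref$psi[, "Est."]), tolerance = 1e-2)
})

test_that("npsi = 3 knots bracket the growth phase of a 5-phase curve", {
  sim <- generate_growth_curves(synth_config(n_wells = 1, noise_sd = 0,
                                             duration = 30))
  ds <- sim$dataset
  fit <- fit_segmented(ds$time, ds$impedance[, 1], npsi = 3)
  fdm <- sim$truth$steepest[1]
  expect_lt(fit$psi[1], fdm)          # one knot before the steepest point
  expect_gt(fit$psi[3], fdm)          # one knot after it
})

test_that("smoothing spline reproduces lines and smooth sigmoids", {
  t <- seq(0, 10, by = 0.25)
  lin <- fit_spline(t, 2 * t + 1)
  expect_lt(max(abs(predict(lin, t) - (2 * t + 1))), 1e-8)
  expect_lt(max(abs(predict(lin, t, deriv = 2L))), 1e-6)

  ts <- seq(0, 20, by = 0.1)
  y <- f4pl(ts, 0, 1, -1, 10)
  sp <- fit_spline(ts, y)
  expect_lt(max(abs(predict(sp, ts) - y)), 1e-3)  # within 1e-3 x range

  expect_error(fit_spline(c(1, 2, 2, 3), 1:4), "duplicate")
  expect_error(fit_spline(1:3, 1:3), "4 points")
})

test_that("the spline adapts to irregular plateaus better than the 4PL", {
  sim <- generate_growth_curves(synth_config(n_wells = 1, noise_sd = 0,
                                             osc_amp = 0.08, osc_period = 4,
                                             duration = 30))
  t <- sim$dataset$time; y <- sim$dataset$impedance[, 1]
  expect_lt(fit_spline(t, y)$gof$rmse, fit_logistic4(t, y)$gof$rmse)
})

test_that("goodness-of-fit measures match hand computation", {
  g <- goodness_of_fit(c(1, -1, 1, -1), p = 1)
  expect_equal(g$rmse, 1)
  expect_equal(g$rv, 4 / 3)

  z <- goodness_of_fit(rep(0, 10), p = 2, y = 1:10)
  expect_equal(z$rmse, 0)
  expect_equal(z$r2, 1)
  expect_true(is.finite(z$aic))

  expect_error(goodness_of_fit(c(0.1, 0.2), p = 2), "n > p")
})

test_that("Akaike weights follow the closed form and sum to one", {
  expect_equal(akaike_weights(c(3, 3, 3)), rep(1 / 3, 3))
  w <- akaike_weights(c(0, 2))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(sum(akaike_weights(c(-24.11, -17.26, -29.71))), 1)
  expect_error(akaike_weights(c(1, NA)), "finite")
  expect_error(akaike_weights(5), "at least 2")

  # ranking is invariant under a common affine rescaling of y for models
  # with equal parameter count
  set.seed(8)
  x <- seq(0, 10, by = 0.25)
  y <- 2 + x + 0.3 * x^2 + rnorm(length(x), 0, 0.5)
  for (sc in c(1, 7.3)) {
    a1 <- fit_polynomial(x, sc * y, 1)$gof$aic
    a2 <- fit_polynomial(x, sc * y, 2)$gof$aic
    expect_lt(a2, a1)
  }
})
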