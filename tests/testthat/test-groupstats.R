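test_that("exponential decay/growth trend fits recover noiseless truth", {
  x <- c(100000, 75000, 56250, 42188, 31641, 23731, 17798, 13348)
  y <- (40 - 20) * exp(-1e-4 * x) + 20
  fit <- fit_exp_decay(x, y)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$par - c(y0 = 40, yb = 20, k = 1e-4)) /
                c(40, 20, 1e-4)), 1e-6)

  flat <- fit_exp_decay(x, rep(30, 8))
  expect_true(flat$degenerate)

  g <- fit_exp_growth(x, 4 / (1 + exp(0.5 + 1e-4 * x)))
  expect_true(g$converged)
  expect_lt(max(abs(g$par - c(ymax = 4, a = 0.5, b = 1e-4)) /
                c(4, 0.5, 1e-4)), 1e-6)
  # asymptotes: y -> 0 as x -> Inf (b > 0), y -> ymax as x -> -Inf
  expect_lt(g$predfun(g$par, 1e9), 1e-6)
  expect_equal(g$predfun(g$par, -1e9), g$par[["ymax"]])
})

test_that("polynomial fits are exact on polynomial data and win AIC", {
  x <- seq(0, 10, by = 0.5)
  f <- fit_polynomial(x, 2 * x + 1, degree = 1)
  expect_equal(unname(f$par), c(1, 2), tolerance = 1e-10)
  expect_equal(f$gof$r2, 1)

  # quadratic data: Akaike weight concentrates on degree 2
  yq <- 0.5 + 0.2 * x + 0.4 * x^2
  w <- akaike_weights(c(linear = fit_polynomial(x, yq, 1)$gof$aic,
                        quadratic = fit_polynomial(x, yq, 2)$gof$aic))
  expect_gt(w[["quadratic"]], 0.95)

  # model-class selection is reliable across noiseless trials
  set.seed(13)
  hits <- 0L
  for (i in 1:20) {
    cf <- rnorm(3)
    cf[3] <- sign(cf[3]) * max(abs(cf[3]), 0.1)
    yy <- cf[1] + cf[2] * x + cf[3] * x^2
    a <- c(fit_polynomial(x, yy, 1)$gof$aic, fit_polynomial(x, yy, 2)$gof$aic)
    hits <- hits + (which.max(akaike_weights(a)) == 2L)
  }
  expect_gte(hits, 19L)
})

test_that("Welch/Bonferroni comparisons behave at both extremes", {
  g <- welch_bonferroni(c(1, 2, 3, 1, 2, 3), rep(c("ctrl", "t1"), each = 3),
                        "ctrl")
  expect_equal(g$t, 0)
  expect_equal(g$p, 1)

  set.seed(21)
  sig <- 0L
  for (i in 1:200) {
    v <- c(rnorm(20, 0), rnorm(20, 3))
    r <- welch_bonferroni(v, rep(c("c", "t"), each = 20), "c")
    sig <- sig + (r$p_adj < 0.001)
  }
  expect_gt(sig / 200, 0.95)

  expect_error(welch_bonferroni(1:4, c("a", "a", "b", "b"), "z"),
               "not found")
  expect_error(welch_bonferroni(1:3, c("a", "a", "b"), "a"), "n >= 2")
  r0 <- welch_bonferroni(c(1, 1, 1, 1), rep(c("a", "b"), each = 2), "a")
  expect_match(r0$note, "zero variance")

  # Bonferroni factor equals the number of tested pairs
  v <- rnorm(30)
  r3 <- welch_bonferroni(v, rep(c("c", "t1", "t2"), each = 10), "c")
  expect_equal(r3$p_adj, pmin(1, r3$p * 2))
})

test_that("delta-method intervals match OLS closed forms on linear fits", {
  set.seed(1)
  x <- 1:20
  y <- 2 + 0.5 * x + rnorm(20)
  fit <- fit_polynomial(x, y, 1)
  grid <- c(3.3, 10, 17.7)
  mine <- predict_intervals(fit, grid)
  lmf <- stats::lm(y ~ x)
  ci <- stats::predict(lmf, data.frame(x = grid), interval = "confidence")
  pi <- stats::predict(lmf, data.frame(x = grid), interval = "prediction")
  expect_lt(max(abs(mine$ci_lower - ci[, "lwr"])), 1e-8)
  expect_lt(max(abs(mine$ci_upper - ci[, "upr"])), 1e-8)
  expect_lt(max(abs(mine$pi_lower - pi[, "lwr"])), 1e-8)
  expect_lt(max(abs(mine$pi_upper - pi[, "upr"])), 1e-8)

  # PI contains CI; higher level widens both
  expect_true(all(mine$pi_lower <= mine$ci_lower))
  wider <- predict_intervals(fit, grid, level = 0.99)
  expect_true(all(wider$ci_upper - wider$ci_lower >
                  mine$ci_upper - mine$ci_lower))

  # zero-noise fit: CI width collapses
  xs <- c(100000, 50000, 25000, 12500, 6000)
  fz <- fit_exp_decay(xs, (30 - 10) * exp(-5e-5 * xs) + 10)
  iv <- predict_intervals(fz, xs)
  expect_lt(max(iv$ci_upper - iv$ci_lower), 1e-3)
})
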