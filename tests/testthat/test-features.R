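test_that("logistic derivative maxima match closed forms and grid oracle", {
  t <- seq(0, 20, by = 0.1)
  fit <- fit_logistic4(t, f4pl(t, 0, 1, -1, 10))
  dm <- derivative_maxima(fit)
  expect_equal(dm$x_fdm, 10, tolerance = 1e-6)
  expect_equal(dm$y_fdm, 0.25, tolerance = 1e-6)  # -b(d - c)/4
  expect_equal(dm$x_sdm, 10 - log(2 + sqrt(3)), tolerance = 1e-6)

  # independent dense-grid oracle on the true curve derivatives
  # (h = 1e-3: truncation O(h^2) = 1e-6 without round-off amplification)
  h <- 1e-3
  d1 <- function(x) (f4pl(x + h, 0, 1, -1, 10) -
                     f4pl(x - h, 0, 1, -1, 10)) / (2 * h)
  o1 <- oracle_argmax(d1, c(0, 20))
  expect_lt(abs(dm$x_fdm - o1$x), 1e-4)
  d2 <- function(x) (d1(x + h) - d1(x - h)) / (2 * h)
  o2 <- oracle_argmax(d2, c(0, 20))
  expect_lt(abs(dm$x_sdm - o2$x), 1e-4)
})

test_that("fractional crossing times match closed forms across models", {
  t <- seq(-10, 10, by = 0.1)
  fit <- fit_logistic4(t, f4pl(t, 0, 1, -1, 0))
  ct <- crossing_times(fit, c(0.1, 0.2, 0.5))
  expect_equal(ct$x[1], -log(9), tolerance = 1e-6)  # e + ln((1-q)/q)/b
  expect_equal(ct$x[3], 0, tolerance = 1e-6)        # 50% rise at x = e
  expect_error(crossing_times(fit, c(0, 0.5)), "inside")

  # monotone curve: crossing times are ordered for every model
  sim <- generate_growth_curves(synth_config(n_wells = 1, noise_sd = 0,
                                             duration = 30))
  tt <- sim$dataset$time; y <- sim$dataset$impedance[, 1]
  for (fit in list(fit_spline(tt, y), fit_logistic4(tt, y),
                   fit_segmented(tt, y, 3))) {
    x <- crossing_times(fit, c(0.1, 0.2, 0.5))$x
    expect_false(is.unsorted(x))
  }
})

test_that("spline FDM locates the generator's steepest point", {
  sim <- generate_growth_curves(synth_config(n_wells = 1, noise_sd = 0,
                                             duration = 30))
  fit <- fit_spline(sim$dataset$time, sim$dataset$impedance[, 1])
  dm <- derivative_maxima(fit)
  expect_lt(abs(dm$x_fdm - sim$truth$steepest[1]), 0.1)  # one interval
  expect_identical(dm$orientation, "increasing")
})

test_that("decreasing curves report |derivative| maxima with a flag", {
  t <- seq(0, 20, by = 0.1)
  fit <- fit_logistic4(t, f4pl(t, 1, 0, -1, 10))   # decaying trace
  dm <- derivative_maxima(fit)
  expect_identical(dm$orientation, "decreasing")
  expect_gt(dm$y_fdm, 0)
  sp <- fit_spline(t, f4pl(t, 1, 0, -1, 10))
  dms <- derivative_maxima(sp)
  expect_identical(dms$orientation, "decreasing")
  expect_equal(dms$x_fdm, 10, tolerance = 0.1)
})

test_that("segment_table reports knots, slopes and the baseline flag", {
  tt <- seq(0, 30, by = 0.1)
  y <- 2 + pmax(tt - 5, 0) * 2
  fit <- fit_segmented(tt, y, npsi = 1)
  tab <- segment_table(fit)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$slope, c(0, 2), tolerance = 1e-6)
  expect_equal(tab$intercept[1], 2, tolerance = 1e-6)
  expect_true(tab$is_baseline[1])

  sim <- generate_growth_curves(synth_config(n_wells = 1, noise_sd = 0,
                                             duration = 30))
  f3 <- fit_segmented(sim$dataset$time, sim$dataset$impedance[, 1], 3)
  t3 <- segment_table(f3)
  expect_equal(nrow(t3), 4)
  expect_length(attr(t3, "psi"), 3)
  expect_true(t3$is_baseline[1])   # flat pre-onset region detected
})

test_that("param table covers all wells, models and reference points", {
  sim <- generate_growth_curves(synth_config(n_wells = 6, duration = 30,
                                             seed = 4))
  nds <- normalize_unit(sim$dataset)
  tab <- quiet_param_table(nds, models = "all")
  expect_equal(nrow(tab), 6)
  need <- c("x.fdm.spline", "y.fdm.spline", "x.sdm.spline", "x01.spline",
            "x.fdm.log", "x01.log", "coef.log.b", "coef.log.c",
            "coef.log.d", "coef.log.e", "slope.log", "x01.seg", "p02.seg",
            "x05.seg", "psi1.seg", "psi3.seg", "slope1.seg",
            "intercept1.seg", "baseline.seg")
  expect_true(all(need %in% names(tab)))
  expect_true(all(tab$status == "ok"))
  expect_false(anyNA(tab[, need]))
  # p0X.seg are aliases of x0X.seg
  expect_equal(tab$p02.seg, tab$x02.seg)
  # time-valued features stay inside the fitted range
  expect_true(all(tab$x01.spline >= 0 & tab$x01.spline <= 30))

  flat <- ecis_dataset(sim$dataset$time,
                       cbind(sim$dataset$impedance[, 1:2],
                             F1 = rep(1, n_timepoints(sim$dataset))),
                       c("W1", "W2", "F1"))
  tf <- quiet_param_table(flat, models = "spl")
  expect_identical(tf$status[tf$well == "F1"], "degenerate")
  expect_true(is.na(tf$x01.spline[tf$well == "F1"]))
})

test_that("features are shift-equivariant and scale as expected", {
  sim <- generate_growth_curves(synth_config(n_wells = 1, noise_sd = 0.005,
                                             duration = 30, seed = 6))
  ds <- sim$dataset
  delta <- 3.7
  shifted <- ecis_dataset(ds$time + delta, ds$impedance, ds$wells, ds$meta)
  a <- quiet_param_table(ds, models = c("spl", "log"))
  b <- quiet_param_table(shifted, models = c("spl", "log"))
  for (col in c("x.fdm.spline", "x01.spline", "x.fdm.log", "x01.log",
                "coef.log.e"))
    expect_equal(b[[col]], a[[col]] + delta, tolerance = 1e-3)
  expect_equal(b$slope.log, a$slope.log, tolerance = 1e-6)

  # unit scaling leaves spline x features, scales y features by 1/range
  nds <- normalize_unit(ds)
  c_ <- quiet_param_table(nds, models = "spl")
  rng <- diff(range(ds$impedance[, 1]))
  expect_equal(c_$x01.spline, a$x01.spline, tolerance = 0.05)
  expect_equal(c_$y.fdm.spline, a$y.fdm.spline / rng, tolerance = 0.02)
})
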