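#' First and second derivative maxima of a fitted curve
#'
#' The first derivative maximum (FDM) is the point of fastest impedance
#' change — the steepest part of the growth phase; the second derivative
#' maximum (SDM) is the point of strongest acceleration, marking the
#' take-off from the baseline. For a logistic fit both are available in
#' closed form (`x_fdm = e`, slope `-b(d - c)/4`,
#' `x_sdm = e + log(2 + sqrt(3))/b`); for a spline they are located by a
#' 2000-point grid scan refined by local optimization. On a
#' monotone-decreasing curve the maxima of the absolute derivatives are
#' returned with `orientation = "decreasing"`.
#'
#' @param fit An `ecis_logfit` or `ecis_splinefit`.
#' @return A list: `x_fdm`, `y_fdm` (the maximal first-derivative value),
#'   `x_sdm`, `y_sdm` (the maximal second-derivative value), `orientation`.
#' @export
derivative_maxima <- function(fit) UseMethod("derivative_maxima")

#' @export
derivative_maxima.ecis_logfit <- function(fit) {
  p <- fit$par
  if (anyNA(p)) stop("unconverged logistic fit", call. = FALSE)
  s <- if (-p[["b"]] * (p[["d"]] - p[["c"]]) >= 0) 1 else -1
  x_sdm <- p[["e"]] + log(2 + sqrt(3)) / p[["b"]]
  list(x_fdm = unname(p[["e"]]),
       y_fdm = s * logistic4(p[["e"]], p[["c"]], p[["d"]], p[["b"]],
                             p[["e"]], deriv = 1L),
       x_sdm = unname(x_sdm),
       y_sdm = s * logistic4(x_sdm, p[["c"]], p[["d"]], p[["b"]], p[["e"]],
                             deriv = 2L),
       orientation = if (s > 0) "increasing" else "decreasing")
}

#' @export
derivative_maxima.ecis_splinefit <- function(fit) {
  rng <- range(fit$t)
  s <- if (fit$fitted[length(fit$fitted)] >= fit$fitted[1]) 1 else -1
  f1 <- .argmax_on_grid(function(x) s * predict(fit, x, deriv = 1L), rng)
  f2 <- .argmax_on_grid(function(x) s * predict(fit, x, deriv = 2L), rng)
  list(x_fdm = f1$x, y_fdm = f1$value, x_sdm = f2$x, y_sdm = f2$value,
       orientation = if (s > 0) "increasing" else "decreasing")
}

# Deterministic dense-grid scan (2000 points) + local refinement.
.argmax_on_grid <- function(f, rng, n_grid = 2000L) {
  xs <- seq(rng[1], rng[2], length.out = n_grid)
  v <- f(xs)
  i <- which.max(v)
  lo <- xs[max(1L, i - 1L)]
  hi <- xs[min(n_grid, i + 1L)]
  if (hi > lo) {
    opt <- stats::optimize(f, c(lo, hi), maximum = TRUE,
                           tol = 1e-10 * diff(rng))
    if (opt$objective >= v[i]) return(list(x = opt$maximum,
                                           value = opt$objective))
  }
  list(x = xs[i], value = v[i])
}

#' Times at fractional impedance rise
#'
#' For each requested fraction `q` the crossing time `x_q` solves
#' `fitted(x) = low + q * (high - low)`, taking the first crossing from the
#' left. The low/high span is the fitted amplitude: the asymptotes `(c, d)`
#' for a logistic fit (closed form `x_q = e + log((1 - q)/q)/b`), the
#' min/max of the fitted values for a spline, and the fitted end levels for
#' a segmented fit (inverted segment by segment). The local slope at the
#' crossing is returned alongside.
#'
#' @param fit An `ecis_logfit`, `ecis_splinefit` or `ecis_segfit`.
#' @param fractions Fractions in (0, 1); default `c(0.1, 0.2, 0.5)` — the
#'   10%, 20% and 50% rise times.
#' @return A data.frame with columns `fraction`, `x`, `slope`.
#' @export
crossing_times <- function(fit, fractions = c(0.1, 0.2, 0.5)) {
  if (any(fractions <= 0 | fractions >= 1))
    stop("fractions must lie strictly inside (0, 1)", call. = FALSE)
  UseMethod("crossing_times")
}

#' @export
crossing_times.ecis_logfit <- function(fit, fractions = c(0.1, 0.2, 0.5)) {
  p <- fit$par
  if (anyNA(p)) stop("unconverged logistic fit", call. = FALSE)
  x <- p[["e"]] + log((1 - fractions) / fractions) / p[["b"]]
  data.frame(fraction = fractions, x = unname(x),
             slope = logistic4(x, p[["c"]], p[["d"]], p[["b"]], p[["e"]],
                               deriv = 1L))
}

#' @export
crossing_times.ecis_splinefit <- function(fit,
                                          fractions = c(0.1, 0.2, 0.5)) {
  rng <- range(fit$t)
  xs <- seq(rng[1], rng[2], length.out = 2000L)
  v <- predict(fit, xs)
  .crossings_numeric(function(x) predict(fit, x),
                     function(x) predict(fit, x, deriv = 1L),
                     xs, v, fractions)
}

#' @export
crossing_times.ecis_segfit <- function(fit, fractions = c(0.1, 0.2, 0.5)) {
  xs <- sort(unique(c(range(fit$t), fit$psi)))
  v <- predict(fit, xs)
  low <- v[1]; high <- v[length(v)]
  if (low > high) { tmp <- low; low <- high; high <- tmp }
  out <- lapply(fractions, function(q) {
    lev <- low + q * (high - low)
    for (k in seq_len(length(xs) - 1L)) {
      v0 <- v[k]; v1 <- v[k + 1]
      if ((v0 - lev) * (v1 - lev) <= 0 && v0 != v1) {
        x <- xs[k] + (lev - v0) * (xs[k + 1] - xs[k]) / (v1 - v0)
        return(c(x = x, slope = predict(fit, x, deriv = 1L)))
      }
    }
    c(x = NA_real_, slope = NA_real_)
  })
  out <- do.call(rbind, out)
  data.frame(fraction = fractions, x = out[, "x"], slope = out[, "slope"])
}

.crossings_numeric <- function(f, f1, xs, v, fractions) {
  low <- min(v); high <- max(v)
  out <- lapply(fractions, function(q) {
    lev <- low + q * (high - low)
    d <- v - lev
    k <- which(d[-length(d)] * d[-1] <= 0)
    if (length(k) == 0L) return(c(x = NA_real_, slope = NA_real_))
    k <- k[1]
    x <- if (d[k] == 0) xs[k]
         else stats::uniroot(function(z) f(z) - lev, c(xs[k], xs[k + 1]),
                             tol = 1e-10 * diff(range(xs)))$root
    c(x = x, slope = f1(x))
  })
  out <- do.call(rbind, out)
  data.frame(fraction = fractions, x = out[, "x"], slope = out[, "slope"])
}

#' Tabulate the segments of a broken-line fit
#'
#' One row per linear segment with its time span, slope and intercept, plus
#' the knot positions. A near-zero slope on the first segment flags it as
#' the baseline region; the first intercept is the fitted baseline value.
#'
#' @param fit A converged `ecis_segfit`.
#' @param baseline_tol First-segment slope magnitudes below
#'   `baseline_tol * max(|slopes|)` are flagged as baseline; default 0.05.
#' @return A data.frame (`segment`, `t_start`, `t_end`, `slope`,
#'   `intercept`, `is_baseline`) with attributes `psi` and
#'   `baseline_intercept`.
#' @export
segment_table <- function(fit, baseline_tol = 0.05) {
  stopifnot(inherits(fit, "ecis_segfit"))
  if (!fit$converged)
    stop("segmented fit did not converge; no segment table", call. = FALSE)
  bounds <- c(min(fit$t), fit$psi, max(fit$t))
  k <- fit$npsi + 1L
  tab <- data.frame(segment = seq_len(k),
                    t_start = bounds[seq_len(k)],
                    t_end = bounds[seq_len(k) + 1L],
                    slope = fit$slopes, intercept = fit$intercepts,
                    is_baseline = FALSE)
  tab$is_baseline[1] <- abs(fit$slopes[1]) <=
    baseline_tol * max(abs(fit$slopes))
  attr(tab, "psi") <- fit$psi
  attr(tab, "baseline_intercept") <- fit$intercepts[1]
  tab
}

.frac_name <- function(q) sprintf("%02d", as.integer(round(q * 10)))

#' Fit all models per well and assemble the reference-point table
#'
#' Runs the requested curve models on every well and collects the complete
#' feature set into one row per well: derivative maxima (`x.fdm.spline`,
#' `y.fdm.spline`, ..., `x.fdm.log`, ...), fractional rise times
#' (`x01.spline`, `x01.log`, `x01.seg`/`p01.seg` with their slopes),
#' logistic coefficients (`coef.log.c` and `coef.log.d` being the averaged
#' baseline and plateau impedance, `coef.log.b`, `coef.log.e`,
#' `slope.log` at the inflection) and the segmented knots, slopes and
#' intercepts (`psi1.seg`, `slope1.seg`, `intercept1.seg`, ...). The
#' `p0X.seg` columns are aliases of `x0X.seg`. Wells where a model fails
#' get missing values and a `status` note, never silent zeros, and never
#' abort the batch. If `meta$normalized` is `TRUE` the (0, 1) scaling is
#' recognized automatically; otherwise a message recommends normalizing
#' before logistic fitting.
#'
#' @param ds An [ecis_dataset].
#' @param models Subset of `c("spl", "log", "seg")` (or `"all"`).
#' @param npsi Knot count for the segmented model; default 3.
#' @param fractions Rise fractions; default `c(0.1, 0.2, 0.5)`.
#' @return A data.frame of class `ecis_param_table`, one row per well.
#' @export
build_param_table <- function(ds, models = c("spl", "log", "seg"),
                              npsi = 3L, fractions = c(0.1, 0.2, 0.5)) {
  validate_ecis_dataset(ds)
  if (identical(models, "all")) models <- c("spl", "log", "seg")
  models <- match.arg(models, c("spl", "log", "seg"), several.ok = TRUE)
  if ("log" %in% models && !isTRUE(ds$meta$normalized))
    message("note: impedance data are not (0, 1)-normalized; ",
            "normalize_unit() is recommended before logistic fitting")
  fn <- .frac_name(fractions)
  rows <- lapply(seq_along(ds$wells), function(j) {
    t <- ds$time
    y <- ds$impedance[, j]
    row <- list(well = ds$wells[j], status = "ok")
    if (diff(range(y)) <= 0) {
      row$status <- "degenerate"
      return(row)
    }
    if ("spl" %in% models) {
      res <- tryCatch({
        fit <- fit_spline(t, y)
        dm <- derivative_maxima(fit)
        ct <- crossing_times(fit, fractions)
        out <- list(x.fdm.spline = dm$x_fdm, y.fdm.spline = dm$y_fdm,
                    x.sdm.spline = dm$x_sdm, y.sdm.spline = dm$y_sdm)
        for (i in seq_along(fractions))
          out[[paste0("x", fn[i], ".spline")]] <- ct$x[i]
        out$rmse.spline <- fit$gof$rmse
        out$aic.spline <- fit$gof$aic
        out
      }, error = function(e) list())
      if (length(res) == 0L) row$status <- "spl failed"
      row <- c(row, res)
    }
    if ("log" %in% models) {
      res <- tryCatch({
        fit <- fit_logistic4(t, y)
        if (!fit$converged) stop("no convergence")
        dm <- derivative_maxima(fit)
        ct <- crossing_times(fit, fractions)
        out <- list(x.fdm.log = dm$x_fdm, y.fdm.log = dm$y_fdm,
                    x.sdm.log = dm$x_sdm, y.sdm.log = dm$y_sdm,
                    coef.log.c = unname(fit$par[["c"]]),
                    coef.log.d = unname(fit$par[["d"]]),
                    coef.log.b = unname(fit$par[["b"]]),
                    coef.log.e = unname(fit$par[["e"]]),
                    slope.log = unname(logistic4(fit$par[["e"]],
                                                 fit$par[["c"]],
                                                 fit$par[["d"]],
                                                 fit$par[["b"]],
                                                 fit$par[["e"]],
                                                 deriv = 1L)))
        for (i in seq_along(fractions))
          out[[paste0("x", fn[i], ".log")]] <- ct$x[i]
        out$rmse.log <- fit$gof$rmse
        out$aic.log <- fit$gof$aic
        out
      }, error = function(e) list())
      if (length(res) == 0L)
        row$status <- paste(setdiff(c(row$status, "log failed"), "ok"),
                            collapse = "; ")
      row <- c(row, res)
    }
    if ("seg" %in% models) {
      res <- tryCatch({
        fit <- fit_segmented(t, y, npsi = npsi)
        ct <- crossing_times(fit, fractions)
        out <- list()
        for (i in seq_along(fractions)) {
          out[[paste0("x", fn[i], ".seg")]] <- ct$x[i]
          out[[paste0("p", fn[i], ".seg")]] <- ct$x[i]
          out[[paste0("slope", fn[i], ".seg")]] <- ct$slope[i]
        }
        for (k in seq_len(fit$npsi))
          out[[paste0("psi", k, ".seg")]] <- fit$psi[k]
        for (k in seq_len(fit$npsi + 1L)) {
          out[[paste0("slope", k, ".seg")]] <- fit$slopes[k]
          out[[paste0("intercept", k, ".seg")]] <- fit$intercepts[k]
        }
        out$baseline.seg <- fit$intercepts[1]
        out$rmse.seg <- fit$gof$rmse
        out$aic.seg <- fit$gof$aic
        out
      }, error = function(e) list())
      if (length(res) == 0L)
        row$status <- paste(setdiff(c(row$status, "seg failed"), "ok"),
                            collapse = "; ")
      row <- c(row, res)
    }
    row
  })
  cols <- setdiff(unique(unlist(lapply(rows, names))),
                  c("well", "status"))
  tab <- as.data.frame(lapply(cols, function(cn) {
    vapply(rows, function(r)
      if (is.null(r[[cn]])) NA_real_ else as.numeric(r[[cn]]),
      numeric(1), USE.NAMES = FALSE)
  }), col.names = cols, check.names = FALSE)
  tab$well <- vapply(rows, `[[`, character(1), "well")
  tab$status <- vapply(rows, `[[`, character(1), "status")
  tab <- tab[, c("well", "status", cols)]
  class(tab) <- c("ecis_param_table", "data.frame")
  tab
}

#' Write a parameter table to CSV or JSON
#'
#' @param tab An `ecis_param_table` (or any data.frame).
#' @param path Output path ending in `.csv` or `.json`.
#' @return Invisibly, `path`.
#' @export
write_param_table <- function(tab, path) {
  if (tolower(tools::file_ext(path)) == "json")
    jsonlite::write_json(tab, path, dataframe = "rows", digits = NA,
                         na = "null")
  else
    utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
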