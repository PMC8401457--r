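#' Exponential trend models across a dilution series
#'
#' `fit_exp_decay()` fits \eqn{y = (y_0 - y_b) e^{-kx} + y_b} — the
#' relation between seeded cell count `x` and the time a curve reference
#' point is reached: many seeded cells reach it early (plateau `y_b`), few
#' seeded cells late (towards `y_0`). `fit_exp_growth()` fits
#' \eqn{y = y_{max} / (1 + \exp(a + bx))}, the mirrored relation used for
#' the AUC versus seeded count. Both use Levenberg-Marquardt least squares
#' with automatic starts.
#'
#' @param x Predictor (e.g. seeded cell count).
#' @param y Response (reference-point time in hours, or AUC).
#' @return An object of class `ecis_trendfit` with elements `type`, `par`,
#'   `gof`, `converged`, `degenerate`, `predfun(par, x)`, `vcov`, `df`,
#'   `sigma2`, `x`, `y`. Non-convergence sets `converged = FALSE`.
#' @export
#' @examples
#' x <- c(100000, 75000, 56250, 42188, 31641, 23731, 17798, 13348)
#' y <- (21 - 15) * exp(-8e-5 * x) + 15
#' fit_exp_decay(x, y)$par
fit_exp_decay <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 4L) stop("need at least 4 points", call. = FALSE)
  predfun <- function(par, x)
    (par[["y0"]] - par[["yb"]]) * exp(-par[["k"]] * x) + par[["yb"]]
  start <- list(y0 = max(y), yb = min(y), k = 1 / stats::median(x))
  .fit_trend("exp_decay", x, y,
             y ~ (y0 - yb) * exp(-k * xx) + yb, start, predfun,
             degenerate = diff(range(y)) <= 1e-10 * max(abs(y), 1))
}

#' @rdname fit_exp_decay
#' @export
fit_exp_growth <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 4L) stop("need at least 4 points", call. = FALSE)
  predfun <- function(par, x)
    par[["ymax"]] / (1 + exp(par[["a"]] + par[["b"]] * x))
  ymax0 <- 1.05 * max(y)
  z <- log(pmax(ymax0 / pmax(y, 1e-12) - 1, 1e-8))
  lin <- stats::lm.fit(cbind(1, x), z)$coefficients
  start <- list(ymax = ymax0, a = unname(lin[1]), b = unname(lin[2]))
  .fit_trend("exp_growth", x, y,
             y ~ ymax / (1 + exp(a + b * xx)), start, predfun,
             degenerate = diff(range(y)) <= 1e-10 * max(abs(y), 1))
}

.fit_trend <- function(type, x, y, formula, start, predfun,
                       degenerate = FALSE) {
  fit <- tryCatch(
    minpack.lm::nlsLM(formula, data = data.frame(xx = x, y = y),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(type = type,
                          par = stats::setNames(rep(NA_real_,
                                                    length(start)),
                                                names(start)),
                          gof = NULL, converged = FALSE,
                          degenerate = degenerate, predfun = predfun,
                          vcov = NULL, df = NA_integer_, sigma2 = NA_real_,
                          x = x, y = y),
                     class = "ecis_trendfit"))
  par <- stats::coef(fit)
  res <- y - predfun(par, x)
  p <- length(par)
  gof <- goodness_of_fit(res, p = p, y = y)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  structure(list(type = type, par = par, gof = gof, converged = TRUE,
                 degenerate = degenerate, predfun = predfun, vcov = vc,
                 df = length(y) - p, sigma2 = gof$rv, x = x, y = y),
            class = "ecis_trendfit")
}

#' @export
print.ecis_trendfit <- function(x, ...) {
  cat(sprintf("%s trend fit%s\n", x$type,
              if (x$degenerate) " (degenerate: flat response)" else ""))
  print(round(x$par, 8))
  if (!is.null(x$gof)) print(x$gof)
  invisible(x)
}

#' Polynomial trend fit
#'
#' Ordinary least squares with a raw polynomial of degree 1 or 2, sharing
#' the package's AIC convention so its fits are comparable with the
#' nonlinear trend models through [akaike_weights].
#'
#' @param x Predictor.
#' @param y Response.
#' @param degree 1 (linear) or 2 (quadratic).
#' @return An `ecis_trendfit` (with `par` the coefficients `b0`, `b1`,
#'   `...` in increasing power).
#' @export
fit_polynomial <- function(x, y, degree = 2L) {
  degree <- as.integer(degree)
  if (!degree %in% 1:2) stop("degree must be 1 or 2", call. = FALSE)
  if (length(x) <= degree + 1L)
    stop("need more than degree + 1 points", call. = FALSE)
  X <- stats::poly(x, degree, raw = TRUE)
  lmfit <- stats::lm(y ~ X)
  cf <- stats::coef(lmfit)
  names(cf) <- paste0("b", 0:degree)
  if (anyNA(cf)) stop("rank-deficient polynomial design", call. = FALSE)
  predfun <- function(par, x) {
    out <- rep(par[["b0"]], length(x))
    for (k in seq_len(length(par) - 1L)) out <- out + par[[k + 1L]] * x^k
    out
  }
  res <- stats::residuals(lmfit)
  p <- degree + 1L
  gof <- goodness_of_fit(res, p = p, y = y)
  vc <- suppressWarnings(stats::vcov(lmfit))  # quiet on perfect fits
  dimnames(vc) <- list(names(cf), names(cf))
  structure(list(type = paste0("poly", degree), par = cf, gof = gof,
                 converged = TRUE, degenerate = FALSE, predfun = predfun,
                 vcov = vc, df = length(y) - p, sigma2 = gof$rv,
                 x = x, y = y, lm = lmfit),
            class = "ecis_trendfit")
}

#' Welch t-tests of treatment groups against a control, Bonferroni-corrected
#'
#' One unequal-variance (Welch) t-test per control-versus-treatment pair,
#' with Satterthwaite degrees of freedom; raw p-values are multiplied by
#' the number of tested pairs and capped at 1 (Bonferroni).
#'
#' @param values Numeric vector of the per-well feature (e.g. `x01.spline`
#'   times or AUC values).
#' @param groups Group label per value.
#' @param control Label of the control group.
#' @return A data.frame of class `ecis_group_tests`, one row per pair:
#'   `group`, `control`, `t`, `df`, `p`, `p_adj`, `mean_control`,
#'   `mean_group`, `sd_control`, `sd_group`, `n_control`, `n_group`,
#'   `note`.
#' @export
welch_bonferroni <- function(values, groups, control) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  if (!control %in% groups)
    stop("control group '", control, "' not found", call. = FALSE)
  lv <- setdiff(unique(groups), control)
  if (length(lv) == 0L) stop("no treatment groups to test", call. = FALSE)
  xc <- values[groups == control]
  if (length(xc) < 2L) stop("each group needs n >= 2", call. = FALSE)
  m <- length(lv)
  rows <- lapply(lv, function(g) {
    xg <- values[groups == g]
    if (length(xg) < 2L) stop("each group needs n >= 2", call. = FALSE)
    note <- ""
    if ((stats::sd(xg) == 0 && length(xg) == 2L) ||
        (stats::sd(xc) == 0 && length(xc) == 2L))
      note <- "zero variance with n = 2"
    if (stats::sd(xg) == 0 && stats::sd(xc) == 0) {
      tt <- list(statistic = c(t = 0), parameter = c(df = NA_real_),
                 p.value = if (mean(xg) == mean(xc)) 1 else 0)
      note <- paste(note, "both groups constant")
    } else {
      tt <- stats::t.test(xg, xc, var.equal = FALSE)
    }
    data.frame(group = g, control = control,
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, p_adj = min(1, tt$p.value * m),
               mean_control = mean(xc), mean_group = mean(xg),
               sd_control = stats::sd(xc), sd_group = stats::sd(xg),
               n_control = length(xc), n_group = length(xg),
               note = trimws(note), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ecis_group_tests", "data.frame")
  out
}

#' Confidence and prediction bands for a trend fit
#'
#' First-order (delta-method) intervals: the pointwise standard error of
#' the fitted curve is \eqn{\sqrt{g^T V g}} with `g` the parameter
#' gradient of the model function and `V` the parameter covariance; the
#' prediction interval adds the residual variance. Deterministic (no
#' resampling).
#'
#' @param fit A converged `ecis_trendfit`.
#' @param xgrid Predictor values at which to evaluate.
#' @param level Coverage level, default 0.95.
#' @return A data.frame: `x`, `fit`, `ci_lower`, `ci_upper`, `pi_lower`,
#'   `pi_upper`.
#' @export
predict_intervals <- function(fit, xgrid, level = 0.95) {
  stopifnot(inherits(fit, "ecis_trendfit"))
  if (!fit$converged || is.null(fit$vcov))
    stop("need a converged fit with a parameter covariance", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)",
                                     call. = FALSE)
  par <- fit$par
  pred <- fit$predfun(par, xgrid)
  eps <- pmax(abs(par), 1) * 1e-7
  G <- vapply(seq_along(par), function(k) {
    up <- par; up[k] <- up[k] + eps[k]
    dn <- par; dn[k] <- dn[k] - eps[k]
    (fit$predfun(up, xgrid) - fit$predfun(dn, xgrid)) / (2 * eps[k])
  }, numeric(length(xgrid)))
  G <- matrix(G, nrow = length(xgrid))
  se_fit <- sqrt(pmax(rowSums((G %*% fit$vcov) * G), 0))
  tcrit <- stats::qt(1 - (1 - level) / 2, df = fit$df)
  se_pred <- sqrt(se_fit^2 + fit$sigma2)
  data.frame(x = xgrid, fit = pred,
             ci_lower = pred - tcrit * se_fit,
             ci_upper = pred + tcrit * se_fit,
             pi_lower = pred - tcrit * se_pred,
             pi_upper = pred + tcrit * se_pred)
}
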