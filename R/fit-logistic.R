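#' Four-parameter logistic model
#'
#' The sigmoid \deqn{f(x) = c + \frac{d - c}{1 + \exp(b(x - e))}}
#' with lower asymptote `c`, upper asymptote `d`, slope parameter `b`
#' (1/hours) and inflection time `e` (hours). Under this parametrization an
#' *increasing* growth curve has `b < 0`. `logistic4()` evaluates the curve
#' and its first two derivatives.
#'
#' @param x Time in hours.
#' @param c,d,b,e Model parameters.
#' @param deriv 0, 1 or 2.
#' @return Numeric vector of (derivative) values.
#' @export
logistic4 <- function(x, c, d, b, e, deriv = 0L) {
  u <- exp(b * (x - e))
  switch(as.character(deriv),
         "0" = c + (d - c) / (1 + u),
         "1" = -(d - c) * b * u / (1 + u)^2,
         "2" = -(d - c) * b^2 * u * (1 - u) / (1 + u)^3,
         stop("deriv must be 0, 1 or 2", call. = FALSE))
}

# Empirical crossing time of level `lev` in the direction of growth; linear
# interpolation between the bracketing samples.
.crossing_empirical <- function(t, y, lev) {
  s <- sign(y[length(y)] - y[1])
  if (s == 0) s <- 1
  yy <- s * y
  ll <- s * lev
  i <- which(yy[-1] >= ll & yy[-length(yy)] < ll)
  if (length(i) == 0L) return(NA_real_)
  i <- i[1]
  t[i] + (ll - yy[i]) * (t[i + 1] - t[i]) / (yy[i + 1] - yy[i])
}

#' Fit a four-parameter logistic to one growth curve
#'
#' Least-squares fit of [logistic4] by Levenberg-Marquardt with automatic
#' starting values: `c0 = min(y)`, `d0 = max(y)`, `e0` at the empirical
#' half-range crossing and `b0 = -4/(t90 - t10)` from the empirical 10%/90%
#' crossing times (sign flipped for decreasing curves), with sign-flip and
#' unit-slope restarts if the first attempt fails. Impedance data should be
#' unit-normalized (see [normalize_unit]) before logistic fitting so the
#' asymptotes are well determined.
#'
#' @param t Time in hours (>= 5 points).
#' @param y Impedance values, not constant.
#' @return An object of class `ecis_logfit`: `par` (named `c`, `d`, `b`,
#'   `e`), `gof` ([goodness_of_fit]), `converged`, `fitted`, `t`, `y`.
#'   Non-convergence is reported through `converged = FALSE`, never as an
#'   error, so batch fitting can continue.
#' @export
#' @examples
#' t <- seq(0, 20, by = 0.2)
#' y <- logistic4(t, 0, 1, -1, 10)
#' fit_logistic4(t, y)$par
fit_logistic4 <- function(t, y) {
  stopifnot(length(t) == length(y))
  if (length(t) < 5L) stop("need at least 5 points", call. = FALSE)
  if (diff(range(y)) <= 0) stop("y is constant; nothing to fit",
                                call. = FALSE)
  lo <- min(y); hi <- max(y); rng <- hi - lo
  e0 <- .crossing_empirical(t, y, lo + 0.5 * rng)
  t10 <- .crossing_empirical(t, y, lo + 0.1 * rng)
  t90 <- .crossing_empirical(t, y, lo + 0.9 * rng)
  increasing <- y[length(y)] >= y[1]
  b0 <- if (!is.na(t10) && !is.na(t90) && abs(t90 - t10) > 0)
    -4 / (t90 - t10) else if (increasing) -1 else 1
  if (is.na(e0)) e0 <- stats::median(t)
  starts <- list(c(b = b0), c(b = -b0), c(b = -1), c(b = 1))
  fit <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ c + (d - c) / (1 + exp(b * (x - e))),
                        data = data.frame(x = t, y = y),
                        start = list(c = lo, d = hi, b = s[["b"]], e = e0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    return(structure(list(par = c(c = NA_real_, d = NA_real_, b = NA_real_,
                                  e = NA_real_),
                          gof = NULL, converged = FALSE,
                          fitted = rep(NA_real_, length(t)), t = t, y = y,
                          nls = NULL),
                     class = "ecis_logfit"))
  }
  par <- stats::coef(fit)
  # the parametrization is symmetric under (c, d, b) -> (d, c, -b);
  # canonicalize to c <= d so c is always the lower asymptote
  if (par[["d"]] < par[["c"]]) {
    par[c("c", "d")] <- par[c("d", "c")]
    par[["b"]] <- -par[["b"]]
  }
  res <- y - stats::fitted(fit)
  structure(list(par = par,
                 gof = goodness_of_fit(res, p = 4L, y = y),
                 converged = TRUE, fitted = as.numeric(stats::fitted(fit)),
                 t = t, y = y, nls = fit),
            class = "ecis_logfit")
}

#' @export
predict.ecis_logfit <- function(object, newdata = object$t, deriv = 0L,
                                ...) {
  p <- object$par
  logistic4(newdata, p[["c"]], p[["d"]], p[["b"]], p[["e"]], deriv = deriv)
}

#' @export
print.ecis_logfit <- function(x, ...) {
  cat("4PL fit: c + (d - c)/(1 + exp(b(x - e)))\n")
  print(round(x$par, 6))
  if (!is.null(x$gof)) print(x$gof)
  if (!x$converged) cat("NOT converged\n")
  invisible(x)
}
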