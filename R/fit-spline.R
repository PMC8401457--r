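#' Fit a cubic smoothing spline to one growth curve
#'
#' Wraps [stats::smooth.spline] with the smoothness chosen by generalized
#' cross-validation (GCV) unless an explicit `spar` is supplied. The spline
#' adapts to highly irregular curve shapes (oscillating plateaus, multiple
#' growth waves) that the parametric models cannot follow; values and first
#' and second derivatives are evaluable anywhere on the fitted range.
#'
#' @param t Time in hours (>= 4 distinct points, no duplicates).
#' @param y Impedance values.
#' @param spar Optional smoothing parameter in `[0, 1]` passed through to
#'   `smooth.spline`; `NULL` (default) selects it by GCV.
#' @return An object of class `ecis_splinefit`: `spline` (the
#'   `smooth.spline` object), `gof`, `fitted`, `t`, `y`, `converged`.
#' @export
#' @examples
#' t <- seq(0, 10, by = 0.25)
#' fit_spline(t, sin(t))$gof
fit_spline <- function(t, y, spar = NULL) {
  stopifnot(length(t) == length(y))
  if (length(t) < 4L) stop("need at least 4 points", call. = FALSE)
  if (anyDuplicated(t)) stop("duplicate time values", call. = FALSE)
  sp <- if (is.null(spar))
    stats::smooth.spline(t, y, cv = FALSE, keep.data = FALSE)
  else
    stats::smooth.spline(t, y, spar = spar, keep.data = FALSE)
  fitted <- stats::predict(sp, t)$y
  p <- max(2L, as.integer(round(sp$df)))
  gof <- if (length(t) > p) goodness_of_fit(y - fitted, p = p, y = y)
         else NULL
  structure(list(spline = sp, gof = gof, fitted = fitted, t = t, y = y,
                 converged = TRUE),
            class = "ecis_splinefit")
}

#' @export
predict.ecis_splinefit <- function(object, newdata = object$t, deriv = 0L,
                                   ...) {
  stats::predict(object$spline, newdata, deriv = deriv)$y
}

#' @export
print.ecis_splinefit <- function(x, ...) {
  cat(sprintf("cubic smoothing spline, equivalent df %.2f, spar %.3f\n",
              x$spline$df, x$spline$spar))
  if (!is.null(x$gof)) print(x$gof)
  invisible(x)
}
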