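#' Fit a segmented (broken-line) regression with estimated breakpoints
#'
#' Continuous piecewise-linear least squares with `npsi` knots (breakpoints)
#' at estimated positions. The knots are estimated by the classic
#' linearization: the model is refitted with hinge terms \eqn{(x-\psi_k)_+}
#' and step terms \eqn{-I(x>\psi_k)}, and each knot is moved by the
#' step/hinge coefficient ratio \eqn{\gamma_k/\delta_k}, damped by 0.5,
#' until the largest update falls below `1e-4 * range(t)` (at most 50
#' iterations). Initial knots sit at the `npsi` equally spaced quantiles of
#' `t`. With `npsi = 3` on a typical growth curve the knots separate the
#' baseline, growth and plateau regions.
#'
#' @param t Time in hours.
#' @param y Impedance values.
#' @param npsi Number of knots (>= 1); default 3.
#' @return An object of class `ecis_segfit`: `psi` (sorted knots),
#'   `slopes` and `intercepts` (length `npsi + 1`, one per segment),
#'   `gof`, `converged`, `fitted`, `t`, `y`, `npsi`, `iterations`.
#' @export
#' @examples
#' t <- seq(0, 10, by = 0.1)
#' y <- pmax(t - 5, 0) * 2      # flat, then slope 2 after t = 5
#' fit_segmented(t, y, npsi = 1)$psi
fit_segmented <- function(t, y, npsi = 3L) {
  stopifnot(length(t) == length(y))
  npsi <- as.integer(npsi)
  if (npsi < 1L) stop("npsi must be at least 1", call. = FALSE)
  n <- length(t)
  if (n < 2L * (npsi + 2L))
    stop("need at least ", 2L * (npsi + 2L), " points for npsi = ", npsi,
         call. = FALSE)
  rng <- diff(range(t))
  # candidate initial knot sets: quantiles, a uniform grid, and (for
  # npsi > 1) the best (npsi - 1)-knot solution with one extra knot
  # inserted at each segment midpoint -- the latter guarantees the RSS can
  # only go down as knots are added
  starts <- list(as.numeric(stats::quantile(t, seq_len(npsi) / (npsi + 1))),
                 min(t) + rng * seq_len(npsi) / (npsi + 1))
  if (npsi > 1L) {
    prev <- tryCatch(fit_segmented(t, y, npsi - 1L), error = function(e) NULL)
    if (!is.null(prev)) {
      bounds <- c(min(t), prev$psi, max(t))
      for (k in seq_len(npsi))
        starts <- c(starts,
                    list(sort(c(prev$psi,
                                (bounds[k] + bounds[k + 1]) / 2))))
    }
  }
  best <- NULL
  for (psi0 in starts) {
    cand <- .seg_iterate(t, y, psi0, rng)
    for (res in list(cand, .seg_refit(t, y, psi0, rng))) {
      if (is.null(res)) next
      if (is.null(best) || res$rss < best$rss - 1e-12 * max(res$rss, 1))
        best <- res
    }
  }
  psi <- unname(best$psi)
  converged <- best$converged
  it <- best$iterations
  U <- vapply(psi, function(p) pmax(t - p, 0), numeric(n))
  X <- cbind(1, t, U)
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  slopes <- cumsum(c(cf[2], cf[2 + seq_len(npsi)]))
  intercepts <- numeric(npsi + 1L)
  intercepts[1] <- cf[1]
  for (k in seq_len(npsi))
    intercepts[k + 1] <- intercepts[k] - cf[2 + k] * psi[k]
  fitted <- as.numeric(X %*% cf)
  p_eff <- 2L + 2L * npsi  # slopes/intercept plus estimated knot positions
  structure(list(psi = psi, slopes = unname(slopes),
                 intercepts = unname(intercepts), npsi = npsi,
                 gof = goodness_of_fit(y - fitted, p = p_eff, y = y),
                 converged = converged, iterations = it,
                 fitted = fitted, t = t, y = y),
            class = "ecis_segfit")
}

# One damped linearization run from a given knot init; returns the refit
# at the final knots. NULL on a degenerate design.
.seg_iterate <- function(t, y, psi, rng, damp = 0.5, maxit = 50L) {
  n <- length(t)
  lo_lim <- min(t) + 0.02 * rng
  hi_lim <- max(t) - 0.02 * rng
  one_pass <- function(psi, dmp) {
    U <- vapply(psi, function(p) pmax(t - p, 0), numeric(n))
    V <- vapply(psi, function(p) -as.numeric(t > p), numeric(n))
    cf <- tryCatch(stats::lm.fit(cbind(1, t, U, V), y)$coefficients,
                   error = function(e) NULL)
    if (is.null(cf)) return(NULL)
    delta <- cf[2 + seq_along(psi)]
    gamma <- cf[2 + length(psi) + seq_along(psi)]
    delta[is.na(delta)] <- 0
    gamma[is.na(gamma)] <- 0
    step <- dmp * ifelse(abs(delta) > 1e-12, gamma / delta, 0)
    # bounded so a knot cannot jump across the data range in one move
    step <- pmin(pmax(step, -0.2 * rng), 0.2 * rng)
    sort(pmin(pmax(psi + step, lo_lim), hi_lim))
  }
  converged <- FALSE
  it <- 0L
  tol <- 1e-4 * rng
  for (it in seq_len(maxit)) {
    psi_new <- one_pass(psi, damp)
    if (is.null(psi_new)) break
    moved <- max(abs(psi_new - psi))
    psi <- psi_new
    if (moved < tol) { converged <- TRUE; break }
  }
  if (converged) {
    # undamped polish: the damped phase halves the remaining offset each
    # pass, so finish with full steps at a much tighter tolerance
    for (k in seq_len(20L)) {
      psi_new <- one_pass(psi, 1)
      if (is.null(psi_new)) break
      moved <- max(abs(psi_new - psi))
      psi <- psi_new
      if (moved < 1e-7 * rng) break
    }
  }
  out <- .seg_refit(t, y, psi, rng)
  if (!is.null(out)) {
    out$converged <- converged
    out$iterations <- it
  }
  out
}

# Least-squares refit with the knots held fixed (gap-separated, in range).
.seg_refit <- function(t, y, psi, rng) {
  min_gap <- max(2 * stats::median(diff(sort(t))), 1e-8 * rng)
  hi_lim <- max(t) - 0.02 * rng
  psi <- sort(psi)
  for (k in seq_len(length(psi) - 1L))
    if (psi[k + 1] - psi[k] < min_gap) psi[k + 1] <- psi[k] + min_gap
  psi <- pmin(psi, hi_lim)
  U <- vapply(psi, function(p) pmax(t - p, 0), numeric(length(t)))
  fit <- tryCatch(stats::lm.fit(cbind(1, t, U), y), error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  list(psi = psi, rss = sum(fit$residuals^2), converged = TRUE,
       iterations = 0L)
}

#' @export
predict.ecis_segfit <- function(object, newdata = object$t, deriv = 0L,
                                ...) {
  seg <- findInterval(newdata, object$psi) + 1L
  if (deriv == 0L)
    object$intercepts[seg] + object$slopes[seg] * newdata
  else if (deriv == 1L)
    object$slopes[seg]
  else
    rep(0, length(newdata))
}

#' @export
print.ecis_segfit <- function(x, ...) {
  cat(sprintf("segmented fit, %d knot(s) at: %s\n", x$npsi,
              paste(signif(x$psi, 6), collapse = ", ")))
  cat("segment slopes:", paste(signif(x$slopes, 6), collapse = ", "), "\n")
  if (!is.null(x$gof)) print(x$gof)
  if (!x$converged) cat("knot iteration NOT converged\n")
  invisible(x)
}
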