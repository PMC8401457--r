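#' Composite Simpson's rule
#'
#' Numerical integral of sampled `y = f(x)` values by the composite Simpson
#' formula
#' \deqn{\int_a^b f \approx \frac{h}{3}\{f(a) + f(b) +
#'   2[f(x_2) + f(x_4) + \dots] + 4[f(x_1) + f(x_3) + \dots]\},}
#' which is exact for polynomials up to degree 3 on a uniform grid with an
#' even number of intervals. Non-uniform spacing or an odd interval count
#' is handled by linear resampling onto a uniform grid with the smallest
#' even interval count `>= n - 1` (reported via a message so the
#' resampling is on record).
#'
#' @param x Strictly increasing sample locations (hours).
#' @param y Sampled values, same length as `x` (length >= 3).
#' @return The approximate integral (impedance x hours).
#' @export
#' @examples
#' x <- seq(0, 1, length.out = 11)
#' integrate_simpson(x, x^2)   # exactly 1/3
integrate_simpson <- function(x, y) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  if (length(y) != n) stop("x and y lengths differ", call. = FALSE)
  if (is.unsorted(x, strictly = TRUE))
    stop("x must be strictly increasing", call. = FALSE)
  h <- diff(x)
  uniform <- (max(h) - min(h)) <= 1e-8 * mean(h)
  even <- (n - 1L) %% 2L == 0L
  if (!uniform || !even) {
    m <- n - 1L
    if (m %% 2L == 1L) m <- m + 1L
    xu <- seq(x[1], x[n], length.out = m + 1L)
    message(sprintf("integrate_simpson: resampled to %d uniform intervals (h = %.6g)",
                    m, xu[2] - xu[1]))
    y <- stats::approx(x, y, xout = xu)$y
    x <- xu
    n <- m + 1L
  }
  h <- (x[n] - x[1]) / (n - 1L)
  interior <- y[2:(n - 1L)]
  odd <- interior[seq(1L, n - 2L, by = 2L)]     # x1, x3, ...
  evn <- if (n > 3L) interior[seq(2L, n - 2L, by = 2L)] else 0
  h / 3 * (y[1] + y[n] + 4 * sum(odd) + 2 * sum(evn))
}

#' Area under the curve for every well
#'
#' Simpson-rule AUC of each impedance trace. By default the data are
#' (0, 1)-normalized first so wells with different plateau impedance are
#' comparable, and the full common time range is integrated. The upper
#' limit can instead be a fixed time in hours, or `"perwell"`, in which
#' case each well is integrated up to the time it first reaches 99% of its
#' own plateau level (its maximum value).
#'
#' @param ds An [ecis_dataset].
#' @param t_end `"full"` (default), `"perwell"` or a time in hours.
#' @param normalize Normalize to (0, 1) first (default `TRUE`; skipped when
#'   `meta$normalized` is already set).
#' @return A data.frame of class `ecis_auc` with columns `well`, `auc`,
#'   `t_start`, `t_end`, `normalized`.
#' @export
auc_per_well <- function(ds, t_end = "full", normalize = TRUE) {
  validate_ecis_dataset(ds)
  normalized <- isTRUE(ds$meta$normalized)
  if (normalize && !normalized) {
    ds <- normalize_unit(ds)
    normalized <- TRUE
  }
  t <- ds$time
  t_start <- t[1]
  ends <- if (identical(t_end, "full")) {
    rep(t[length(t)], n_wells(ds))
  } else if (identical(t_end, "perwell")) {
    vapply(seq_len(n_wells(ds)), function(j) {
      y <- ds$impedance[, j]
      lev <- min(y) + 0.99 * (max(y) - min(y))
      t[which(y >= lev)[1]]
    }, numeric(1))
  } else if (is.numeric(t_end) && length(t_end) == 1L) {
    if (t_end <= t[2]) stop("t_end must lie after the second timepoint",
                            call. = FALSE)
    rep(min(t_end, t[length(t)]), n_wells(ds))
  } else stop("t_end must be 'full', 'perwell' or a time in hours",
              call. = FALSE)
  auc <- vapply(seq_len(n_wells(ds)), function(j) {
    keep <- t >= t_start & t <= ends[j]
    suppressMessages(integrate_simpson(t[keep], ds$impedance[keep, j]))
  }, numeric(1))
  res <- data.frame(well = ds$wells, auc = auc, t_start = t_start,
                    t_end = ends, normalized = normalized,
                    stringsAsFactors = FALSE)
  class(res) <- c("ecis_auc", "data.frame")
  res
}
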