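#' Goodness-of-fit summary for a fitted curve
#'
#' Computes the standard least-squares fit diagnostics used for model choice
#' between the spline, logistic and segmented fits:
#' \deqn{RMSE = \sqrt{RSS/n}, \quad RV = RSS/(n-p), \quad
#'       R^2 = 1 - RSS/TSS,}
#' \deqn{AIC = n \log(2\pi RSS/n) + n + 2(p+1)}
#' (Gaussian maximum-likelihood convention, error variance counted as a
#' parameter). Both the `/n` and `/(n-p)` residual scalings are reported so
#' either convention can be matched. For numerically perfect fits the RSS is
#' floored at 1e-300 so the AIC stays finite.
#'
#' @param residuals Numeric vector of residuals (observed minus fitted).
#' @param p Number of fitted parameters.
#' @param y Optional observed values, used for the total sum of squares in
#'   `r2` (`NA` if omitted).
#' @param n Number of observations; defaults to `length(residuals)`.
#' @return A list of class `ecis_gof`: `rmse`, `rv`, `r2`, `aic`, `n`, `p`,
#'   `rss`.
#' @export
#' @examples
#' goodness_of_fit(c(1, -1, 1, -1), p = 1)
goodness_of_fit <- function(residuals, p, y = NULL,
                            n = length(residuals)) {
  if (n <= p) stop("need more observations than parameters (n > p)",
                   call. = FALSE)
  rss <- sum(residuals^2)
  r2 <- if (is.null(y)) NA_real_ else {
    tss <- sum((y - mean(y))^2)
    if (tss > 0) 1 - rss / tss else NA_real_
  }
  rss_f <- max(rss, 1e-300)
  structure(list(rmse = sqrt(rss / n), rv = rss / (n - p), r2 = r2,
                 aic = n * log(2 * pi * rss_f / n) + n + 2 * (p + 1),
                 n = n, p = p, rss = rss),
            class = "ecis_gof")
}

#' @export
print.ecis_gof <- function(x, ...) {
  cat(sprintf("RMSE %.4g  RV %.4g  R2 %.4g  AIC %.4g  (n=%d, p=%d)\n",
              x$rmse, x$rv, x$r2, x$aic, x$n, x$p))
  invisible(x)
}

#' Akaike weights for a set of competing models
#'
#' Normalized model-support scores
#' \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)} with
#' \eqn{\Delta_i = AIC_i - \min_j AIC_j}; they sum to one and the best
#' model carries the largest weight.
#'
#' @param aics Numeric vector (length >= 2) of finite AIC values.
#' @return Numeric vector of weights, same names as `aics`.
#' @export
#' @examples
#' akaike_weights(c(linear = 10, quadratic = 2))
akaike_weights <- function(aics) {
  if (length(aics) < 2L) stop("need at least 2 models to compare",
                              call. = FALSE)
  if (any(!is.finite(aics))) stop("all AIC values must be finite",
                                  call. = FALSE)
  d <- aics - min(aics)
  w <- exp(-d / 2)
  w / sum(w)
}
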