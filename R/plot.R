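#' Plot ECIS growth curves
#'
#' Draws the impedance traces either overlaid in one panel or as a grid of
#' per-well panels. Fitted curves and extracted reference points (FDM/SDM
#' markers, fractional-rise levels, segmentation knots) are rendered on top
#' when supplied. When `file` is given the figure is written as PNG (or PDF
#' by extension) instead of drawn on the current device.
#'
#' @param ds An [ecis_dataset].
#' @param fits Optional named list of per-well fit objects (names matching
#'   wells) to overlay.
#' @param features Optional [build_param_table] output; x-valued reference
#'   points of each well are marked with vertical ticks.
#' @param layout `"overlay"` (default) or `"grid"` (one panel per well).
#' @param file Optional output path (`.png` or `.pdf`).
#' @param width,height Device size in pixels (png) or inches (pdf).
#' @return Invisibly, `file` (or `NULL` when drawing to the screen).
#' @export
plot_curves <- function(ds, fits = NULL, features = NULL,
                        layout = c("overlay", "grid"), file = NULL,
                        width = 900, height = 700) {
  validate_ecis_dataset(ds)
  layout <- match.arg(layout)
  if (!is.null(file)) {
    if (tolower(tools::file_ext(file)) == "pdf")
      grDevices::pdf(file, width = width / 96, height = height / 96)
    else
      grDevices::png(file, width = width, height = height, res = 96)
    on.exit(grDevices::dev.off())
  }
  ylab <- if (isTRUE(ds$meta$normalized)) "normalized impedance (0-1)"
          else "impedance (ohm)"
  if (layout == "overlay") {
    graphics::matplot(ds$time, ds$impedance, type = "l", lty = 1,
                      col = grDevices::hcl.colors(max(n_wells(ds), 2),
                                                  "Dark 3"),
                      xlab = "time (h)", ylab = ylab, main = "ECIS curves")
    graphics::legend("bottomright", legend = ds$wells, lty = 1, cex = 0.7,
                     col = grDevices::hcl.colors(max(n_wells(ds), 2),
                                                 "Dark 3"))
    .overlay_marks(ds, fits, features, ds$wells)
  } else {
    nw <- n_wells(ds)
    nc <- ceiling(sqrt(nw))
    nr <- ceiling(nw / nc)
    op <- graphics::par(mfrow = c(nr, nc), mar = c(3.5, 3.5, 2, 0.5),
                        mgp = c(2, 0.7, 0))
    # restore par before any file device closes, so no stray device opens
    on.exit(graphics::par(op), add = TRUE, after = FALSE)
    for (j in seq_len(nw)) {
      graphics::plot(ds$time, ds$impedance[, j], type = "l",
                     xlab = "time (h)", ylab = ylab, main = ds$wells[j])
      .overlay_marks(ds, fits, features, ds$wells[j])
    }
  }
  invisible(file)
}

.overlay_marks <- function(ds, fits, features, wells) {
  for (w in wells) {
    if (!is.null(fits) && !is.null(fits[[w]])) {
      xx <- seq(min(ds$time), max(ds$time), length.out = 300)
      graphics::lines(xx, predict(fits[[w]], xx), col = "black", lwd = 2,
                      lty = 2)
      if (inherits(fits[[w]], "ecis_segfit"))
        graphics::abline(v = fits[[w]]$psi, col = "grey50", lty = 3)
    }
    if (!is.null(features)) {
      row <- features[features$well == w, , drop = FALSE]
      if (nrow(row)) {
        xcols <- grep("^(x|p)", names(row), value = TRUE)
        xv <- unlist(row[1, xcols])
        graphics::abline(v = xv[is.finite(xv)], col = "steelblue",
                         lty = 3)
      }
    }
  }
}

#' @export
plot.ecis_dataset <- function(x, ...) plot_curves(x, ...)
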