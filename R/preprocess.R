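#' Subtract each well's baseline level
#'
#' The baseline is the per-well median of the impedance values inside the
#' chosen window (robust against seeding spikes). Each trace then starts
#' near zero, so wells with different blank-electrode impedance become
#' comparable.
#'
#' @param ds An [ecis_dataset].
#' @param window Either a single count `n` (the first `n` timepoints,
#'   default 5) or a length-2 numeric range in hours `c(t0, t1)`.
#' @return A new `ecis_dataset`; `meta$baseline_window` records the window.
#' @export
subtract_baseline <- function(ds, window = 5L) {
  validate_ecis_dataset(ds)
  if (length(window) == 1L) {
    idx <- seq_len(min(as.integer(window), length(ds$time)))
    if (window < 1L) stop("baseline window is empty", call. = FALSE)
  } else if (length(window) == 2L) {
    idx <- which(ds$time >= window[1] & ds$time <= window[2])
    if (length(idx) == 0L)
      stop("baseline window contains no timepoints", call. = FALSE)
  } else stop("window must be a count or a time range", call. = FALSE)
  base <- apply(ds$impedance[idx, , drop = FALSE], 2L, stats::median)
  meta <- ds$meta
  meta$baseline_window <- paste(range(ds$time[idx]), collapse = "-")
  ecis_dataset(ds$time, sweep(ds$impedance, 2L, base), ds$wells, meta)
}

#' Normalize each well to the (0, 1) interval
#'
#' Per well, `y' = (y - min) / (max - min)`, so every trace spans exactly
#' 0 to 1. Recommended before logistic fitting and before AUC comparison
#' across wells with different plateau impedance. Sets
#' `meta$normalized = TRUE`, which downstream fitting honours
#' automatically.
#'
#' @param ds An [ecis_dataset].
#' @return A new, unit-scaled `ecis_dataset`.
#' @export
normalize_unit <- function(ds) {
  validate_ecis_dataset(ds)
  rng <- apply(ds$impedance, 2L, range)
  flat <- rng[2L, ] - rng[1L, ] <= 0
  if (any(flat))
    stop("cannot normalize flat well(s): ",
         paste(ds$wells[flat], collapse = ", "), call. = FALSE)
  imp <- sweep(sweep(ds$impedance, 2L, rng[1L, ]), 2L,
               rng[2L, ] - rng[1L, ], "/")
  meta <- ds$meta
  meta$normalized <- TRUE
  ecis_dataset(ds$time, imp, ds$wells, meta)
}

#' Flag outlier wells against the plate consensus
#'
#' At each timepoint the plate consensus is the across-well median, with
#' spread measured by the median absolute deviation (MAD). Each well is
#' scored by the median over timepoints of its absolute pointwise robust-z
#' deviation; wells scoring above `threshold` are flagged. Deterministic
#' and permutation-equivariant in the wells.
#'
#' @param ds An [ecis_dataset] with at least 3 wells.
#' @param threshold Robust-z cutoff; default 3.5.
#' @return A data.frame of class `ecis_outlier_report` with columns `well`,
#'   `score`, `flagged`, `threshold`.
#' @export
detect_outlier_wells <- function(ds, threshold = 3.5) {
  validate_ecis_dataset(ds)
  if (n_wells(ds) < 3L)
    stop("outlier detection needs at least 3 wells", call. = FALSE)
  eps <- 1e-12
  med <- apply(ds$impedance, 1L, stats::median)
  mad <- apply(ds$impedance, 1L, stats::mad)
  z <- abs(sweep(ds$impedance, 1L, med)) / (mad + eps)
  score <- apply(z, 2L, stats::median)
  rep <- data.frame(well = ds$wells, score = unname(score),
                    flagged = unname(score > threshold),
                    threshold = threshold, stringsAsFactors = FALSE)
  class(rep) <- c("ecis_outlier_report", "data.frame")
  rep
}
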