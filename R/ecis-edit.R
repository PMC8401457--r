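#' Cut a time range out of a dataset
#'
#' Keeps the rows with `t_min <= t <= t_max` (closed interval). Used e.g. to
#' truncate traces to a common growth window before feature extraction.
#'
#' @param ds An [ecis_dataset].
#' @param t_min,t_max Bounds in hours; `-Inf`/`Inf` keep the respective end.
#' @return A new `ecis_dataset`; the input is never modified.
#' @export
cut_time <- function(ds, t_min = -Inf, t_max = Inf) {
  validate_ecis_dataset(ds)
  if (!(t_min < t_max)) stop("t_min must be smaller than t_max",
                             call. = FALSE)
  keep <- ds$time >= t_min & ds$time <= t_max
  if (sum(keep) < 2L)
    stop("cut would leave fewer than 2 timepoints", call. = FALSE)
  ecis_dataset(ds$time[keep], ds$impedance[keep, , drop = FALSE], ds$wells,
               ds$meta)
}

#' Select or delete wells
#'
#' `select_wells()` builds a new dataset from the named wells in the order
#' given; `delete_wells()` drops them (unknown ids are ignored with a
#' warning) keeping the original order. Together they partition the plate,
#' e.g. splitting medium-control wells from cell-bearing wells.
#'
#' @param ds An [ecis_dataset].
#' @param ids Character vector of well identifiers.
#' @return A new `ecis_dataset`.
#' @export
select_wells <- function(ds, ids) {
  validate_ecis_dataset(ds)
  ids <- as.character(ids)
  unknown <- setdiff(ids, ds$wells)
  if (length(unknown))
    stop("unknown well(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  if (length(ids) == 0L) stop("selection would leave zero wells",
                              call. = FALSE)
  ecis_dataset(ds$time, ds$impedance[, ids, drop = FALSE], ids, ds$meta)
}

#' @rdname select_wells
#' @export
delete_wells <- function(ds, ids) {
  validate_ecis_dataset(ds)
  ids <- as.character(ids)
  absent <- setdiff(ids, ds$wells)
  if (length(absent))
    warning("well(s) not present, ignored: ",
            paste(absent, collapse = ", "), call. = FALSE)
  keep <- setdiff(ds$wells, ids)
  if (length(keep) == 0L) stop("deletion would leave zero wells",
                               call. = FALSE)
  ecis_dataset(ds$time, ds$impedance[, keep, drop = FALSE], keep, ds$meta)
}

#' Combine datasets into one plate
#'
#' Concatenates the wells of two or more datasets, e.g. pooling independent
#' runs of the same treatment into one replicate set. Equal time grids
#' (within 1e-6 h) are used as is; unequal grids are linearly interpolated
#' onto the first dataset's grid restricted to the common time range, which
#' must cover at least half of each dataset's own range. Duplicate well ids
#' are disambiguated by suffixing the dataset index (`A1.2`).
#'
#' @param ... `ecis_dataset` objects, or a single list of them.
#' @return A combined `ecis_dataset` carrying the first dataset's metadata.
#' @export
combine_ecis <- function(...) {
  dss <- list(...)
  if (length(dss) == 1L && !inherits(dss[[1]], "ecis_dataset"))
    dss <- dss[[1]]
  if (length(dss) == 0L) stop("no datasets to combine", call. = FALSE)
  lapply(dss, validate_ecis_dataset)
  if (length(dss) == 1L) return(dss[[1]])
  ref <- dss[[1]]
  same_grid <- all(vapply(dss, function(d)
    length(d$time) == length(ref$time) &&
      max(abs(d$time - ref$time)) <= 1e-6, logical(1)))
  if (same_grid) {
    time <- ref$time
    mats <- lapply(dss, `[[`, "impedance")
  } else {
    lo <- max(vapply(dss, function(d) min(d$time), numeric(1)))
    hi <- min(vapply(dss, function(d) max(d$time), numeric(1)))
    if (!(lo < hi)) stop("datasets have non-overlapping time ranges",
                         call. = FALSE)
    for (d in dss) {
      rng <- diff(range(d$time))
      if ((hi - lo) < 0.5 * rng)
        stop("common time range covers less than 50% of a dataset's range; ",
             "refusing to combine", call. = FALSE)
    }
    time <- ref$time[ref$time >= lo & ref$time <= hi]
    mats <- lapply(dss, function(d) {
      apply(d$impedance, 2L, function(y)
        stats::approx(d$time, y, xout = time)$y)
    })
  }
  wells <- unlist(lapply(dss, `[[`, "wells"))
  if (anyDuplicated(wells)) {
    src <- rep(seq_along(dss), vapply(dss, n_wells, integer(1)))
    dup <- wells %in% wells[duplicated(wells)]
    wells[dup] <- paste(wells[dup], src[dup], sep = ".")
  }
  ecis_dataset(time, do.call(cbind, mats), wells, ref$meta)
}

#' Re-anchor the experiment start at zero
#'
#' Subtracts `t0` (e.g. the seeding time after a baseline recording) from
#' the time grid and drops everything before it, so the new grid starts at
#' 0 h.
#'
#' @param ds An [ecis_dataset].
#' @param t0 New time origin in hours; must lie within the recorded range.
#' @return A new `ecis_dataset` with `time[1] == 0`.
#' @export
shift_start <- function(ds, t0) {
  validate_ecis_dataset(ds)
  if (t0 > max(ds$time) || t0 < min(ds$time))
    stop("t0 = ", t0, " h lies outside the recorded time range",
         call. = FALSE)
  keep <- ds$time >= t0
  time <- ds$time[keep] - t0
  if (time[1] > 0) {  # t0 between samples: still anchor first kept point at 0
    time <- time - time[1]
  }
  ecis_dataset(time, ds$impedance[keep, , drop = FALSE], ds$wells, ds$meta)
}

#' Trim or extend the leading region
#'
#' Removes the first `drop_n` rows and/or prepends a flat synthetic prefix
#' of `extend_hours` hours at each well's first remaining impedance value,
#' sampled on the dataset's median sampling interval. Useful when the
#' recorded baseline is too short (or too long) for downstream fits.
#'
#' @param ds An [ecis_dataset].
#' @param drop_n Number of leading rows to remove.
#' @param extend_hours Length of the flat prefix to prepend, in hours.
#' @return A new `ecis_dataset`.
#' @export
trim_extend_leading <- function(ds, drop_n = 0L, extend_hours = 0) {
  validate_ecis_dataset(ds)
  drop_n <- as.integer(drop_n)
  if (drop_n < 0L || extend_hours < 0)
    stop("drop_n and extend_hours must be non-negative", call. = FALSE)
  if (drop_n >= length(ds$time))
    stop("drop_n must leave at least one timepoint", call. = FALSE)
  keep <- seq_along(ds$time) > drop_n
  time <- ds$time[keep]
  imp <- ds$impedance[keep, , drop = FALSE]
  if (extend_hours > 0) {
    h <- stats::median(diff(ds$time))
    n_pre <- floor(extend_hours / h + 1e-9)
    if (n_pre > 0L) {
      pre_t <- time[1] - h * rev(seq_len(n_pre))
      pre <- matrix(rep(imp[1L, ], each = n_pre), nrow = n_pre)
      time <- c(pre_t, time)
      imp <- rbind(pre, imp)
    }
  }
  ecis_dataset(time, imp, ds$wells, ds$meta)
}
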