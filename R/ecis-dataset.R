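#' ECIS dataset container
#'
#' An `ecis_dataset` holds one well plate worth of impedance-versus-time
#' growth curves: a common time grid in hours, a numeric impedance matrix
#' (one column per well, in ohm unless normalized) and free-form metadata.
#' It is the common currency of every pipeline step in this package.
#'
#' @param time Numeric vector of timepoints in hours, strictly increasing,
#'   finite.
#' @param impedance Numeric matrix with `length(time)` rows and one column
#'   per well; all values finite.
#' @param wells Character vector of unique well identifiers (e.g. `"A1"`).
#'   Defaults to the column names of `impedance`.
#' @param meta Named list of metadata (source file, measurement frequency in
#'   Hz, `normalized` flag, ...).
#'
#' @return An object of class `ecis_dataset` with elements `time`, `wells`,
#'   `impedance` and `meta`.
#' @export
#' @examples
#' ds <- ecis_dataset(0:5, cbind(A1 = c(10, 10, 12, 20, 28, 30)))
#' ds
ecis_dataset <- function(time, impedance, wells = colnames(impedance),
                         meta = list()) {
  time <- as.numeric(time)
  if (is.data.frame(impedance)) impedance <- as.matrix(impedance)
  if (is.null(dim(impedance))) impedance <- matrix(impedance, ncol = 1L)
  storage.mode(impedance) <- "double"
  if (ncol(impedance) == 0L)
    stop("dataset must contain at least one well", call. = FALSE)
  if (is.null(wells)) wells <- paste0("W", seq_len(ncol(impedance)))
  wells <- as.character(wells)
  colnames(impedance) <- wells
  rownames(impedance) <- NULL
  ds <- structure(list(time = time, wells = wells, impedance = impedance,
                       meta = meta),
                  class = "ecis_dataset")
  validate_ecis_dataset(ds)
  ds
}

validate_ecis_dataset <- function(ds) {
  stopifnot(inherits(ds, "ecis_dataset"))
  time <- ds$time
  if (length(time) < 1L || anyNA(time) || any(!is.finite(time)))
    stop("time grid must be finite and non-missing", call. = FALSE)
  if (is.unsorted(time, strictly = TRUE))
    stop("time grid must be strictly increasing", call. = FALSE)
  if (!is.matrix(ds$impedance) || nrow(ds$impedance) != length(time))
    stop("impedance must be a matrix with one row per timepoint",
         call. = FALSE)
  if (ncol(ds$impedance) != length(ds$wells))
    stop("impedance must have one column per well", call. = FALSE)
  if (length(ds$wells) == 0L)
    stop("dataset must contain at least one well", call. = FALSE)
  if (anyDuplicated(ds$wells))
    stop("well identifiers must be unique: ",
         paste(unique(ds$wells[duplicated(ds$wells)]), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(ds$impedance)))
    stop("impedance values must be finite (use read_ecis_table(impute=) ",
         "for gappy exports)", call. = FALSE)
  invisible(ds)
}

#' @export
print.ecis_dataset <- function(x, ...) {
  cat(sprintf("ECIS dataset: %d wells x %d timepoints, %.2f-%.2f h\n",
              length(x$wells), length(x$time), min(x$time), max(x$time)))
  cat("wells:", paste(utils::head(x$wells, 12L), collapse = " "),
      if (length(x$wells) > 12L) "..." else "", "\n")
  if (isTRUE(x$meta$normalized)) cat("normalized to (0, 1)\n")
  if (!is.null(x$meta$frequency_hz))
    cat("measurement frequency:", x$meta$frequency_hz, "Hz\n")
  invisible(x)
}

#' @export
as.data.frame.ecis_dataset <- function(x, ...) {
  data.frame(Time = x$time, x$impedance, check.names = FALSE)
}

#' Number of wells / timepoints
#' @param ds An `ecis_dataset`.
#' @return Integer count.
#' @export
n_wells <- function(ds) length(ds$wells)

#' @rdname n_wells
#' @export
n_timepoints <- function(ds) length(ds$time)
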