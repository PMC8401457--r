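#' Configuration for the synthetic growth-curve generator
#'
#' The generator emulates the five chronological phases of an
#' impedance-based growth curve — flat baseline, exponential take-off,
#' linear growth, saturating transition and plateau — by integrating a
#' smooth bell-shaped growth rate \eqn{r(t) = \sigma(k(t - t_{on}))\,
#' \sigma(-k(t - t_{off}))} (a product of two logistic gates), scaled to
#' the configured amplitude. An optional linear drift and sinusoidal
#' oscillation can be switched on in the plateau, and i.i.d. Gaussian
#' noise (as a fraction of the amplitude) is added on top. Everything is
#' deterministic under `seed`.
#'
#' @param n_wells Number of wells (default 6, one 8-well plate minus the
#'   two medium controls).
#' @param interval Sampling interval in hours (default 0.1, about one
#'   reading every 6 minutes).
#' @param duration Recording length in hours (default 46.9).
#' @param baseline Baseline impedance level in ohm (default 500, a typical
#'   blank gold electrode at 15 kHz).
#' @param amplitude Total impedance rise from baseline to plateau in ohm
#'   (default 1500).
#' @param onset Time of growth take-off in hours (default 10).
#' @param steepness Rate constant `k` of the take-off/saturation gates, in
#'   1/hours (default 1.5).
#' @param growth_duration Length of the active growth window in hours
#'   (default 6).
#' @param plateau_slope Linear drift in the plateau, as amplitude fraction
#'   per hour (default 0).
#' @param osc_amp,osc_period Plateau oscillation amplitude (fraction of
#'   `amplitude`, default 0) and period in hours (default 4).
#' @param noise_sd Gaussian noise standard deviation as a fraction of
#'   `amplitude` (default 0.01).
#' @param seed Integer random seed (default 1).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_wells = 6L, interval = 0.1, duration = 46.9,
                         baseline = 500, amplitude = 1500, onset = 10,
                         steepness = 1.5, growth_duration = 6,
                         plateau_slope = 0, osc_amp = 0, osc_period = 4,
                         noise_sd = 0.01, seed = 1L) {
  cfg <- list(n_wells = as.integer(n_wells), interval = interval,
              duration = duration, baseline = baseline,
              amplitude = amplitude, onset = onset, steepness = steepness,
              growth_duration = growth_duration,
              plateau_slope = plateau_slope, osc_amp = osc_amp,
              osc_period = osc_period, noise_sd = noise_sd,
              seed = as.integer(seed))
  with(cfg, {
    if (interval <= 0 || duration <= 0 || growth_duration <= 0)
      stop("interval, duration and growth_duration must be positive",
           call. = FALSE)
    if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
    if (amplitude <= 0) stop("amplitude must be positive", call. = FALSE)
    if (n_wells < 1L) stop("need at least one well", call. = FALSE)
  })
  class(cfg) <- "synth_config"
  cfg
}

# Noiseless 5-phase shape on an arbitrary grid, for one onset value.
# Returns baseline + amplitude * normalized cumulative growth rate.
.synth_curve <- function(t, cfg, onset = cfg$onset,
                         amplitude = cfg$amplitude) {
  k <- cfg$steepness
  t_off <- onset + cfg$growth_duration
  rate <- stats::plogis(k * (t - onset)) * stats::plogis(-k * (t - t_off))
  # cumulative trapezoid of the rate, normalized over the full window
  cum <- c(0, cumsum((rate[-1] + rate[-length(rate)]) / 2 * diff(t)))
  total <- .rate_total(cfg, onset)
  y <- cfg$baseline + amplitude * cum / total
  gate <- stats::plogis(k * (t - t_off))
  if (cfg$plateau_slope != 0)
    y <- y + amplitude * cfg$plateau_slope * pmax(t - t_off, 0) * gate
  if (cfg$osc_amp != 0)
    y <- y + amplitude * cfg$osc_amp *
      sin(2 * pi * (t - t_off) / cfg$osc_period) * gate
  y
}

# Integral of the rate gate from 0 to infinity is effectively the growth
# window length; evaluate it on a fine grid so amplitude is hit exactly at
# the end of a long recording.
.rate_total <- function(cfg, onset) {
  tt <- seq(0, cfg$duration, by = cfg$interval / 10)
  k <- cfg$steepness
  t_off <- onset + cfg$growth_duration
  rate <- stats::plogis(k * (tt - onset)) * stats::plogis(-k * (tt - t_off))
  sum((rate[-1] + rate[-length(rate)]) / 2 * diff(tt))
}

# Ground-truth reference points from the noiseless curve on a 10x dense
# grid: take-off (onset), steepest point, 10% rise time, plateau level.
.synth_truth <- function(cfg, onset, amplitude = cfg$amplitude) {
  tt <- seq(0, cfg$duration, by = cfg$interval / 10)
  y <- .synth_curve(tt, cfg, onset = onset, amplitude = amplitude)
  d1 <- diff(y) / diff(tt)
  steepest <- tt[which.max(d1)]
  lo <- min(y); hi <- max(y)
  x01 <- tt[which(y >= lo + 0.1 * (hi - lo))[1]]
  list(onset = onset, steepest = steepest, x01 = x01, plateau = hi)
}

#' Generate a synthetic ECIS-like dataset
#'
#' Produces `cfg$n_wells` replicate growth curves under one condition, plus
#' a ground-truth table (true onset, steepest point, 10% rise time and
#' plateau level per well) so every feature-extraction routine can be
#' checked against the generator. The same seed and configuration always
#' reproduce the identical dataset.
#'
#' @param cfg A [synth_config].
#' @return A list: `dataset` (an [ecis_dataset]) and `truth` (data.frame).
#' @export
#' @examples
#' sim <- generate_growth_curves(synth_config(n_wells = 3, duration = 24))
#' sim$truth
generate_growth_curves <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  t <- seq(0, cfg$duration, by = cfg$interval)
  wells <- paste0("W", seq_len(cfg$n_wells))
  clean <- .synth_curve(t, cfg)
  imp <- vapply(seq_len(cfg$n_wells), function(j)
    clean + stats::rnorm(length(t), 0, cfg$noise_sd * cfg$amplitude),
    numeric(length(t)))
  tr <- .synth_truth(cfg, cfg$onset)
  truth <- data.frame(well = wells, onset = tr$onset,
                      steepest = tr$steepest, x01 = tr$x01,
                      plateau = tr$plateau, stringsAsFactors = FALSE)
  list(dataset = ecis_dataset(t, imp, wells,
                              meta = list(source = "synthetic",
                                          frequency_hz = 15000,
                                          seed = cfg$seed)),
       truth = truth)
}

#' Generate a synthetic dilution-series experiment
#'
#' Emulates a seeding dilution series: each seeded cell count `x` shifts
#' the growth onset according to the exponential-decay law
#' \eqn{onset(x) = (o_0 - o_b) e^{-kx} + o_b}: many seeded cells take off
#' early (towards `o_b`), few seeded cells late (towards `o_0`). Each
#' count is seeded in `duplicates` wells on each of
#' `runs` independent plates. The configured `(o0, ob, k)` are returned so
#' end-to-end recovery through feature extraction and [fit_exp_decay] can
#' be asserted.
#'
#' @param cfg A [synth_config]; its `onset` field is overridden per count.
#' @param seeded_counts Vector of seeded cell numbers; the default is the
#'   eight-step half-log-like series 100000, 75000, 56250, 42188, 31641,
#'   23731, 17798, 13348.
#' @param o0,ob Onset at zero / infinitely many seeded cells, hours
#'   (defaults 20 and 14).
#' @param k Onset decay rate per seeded cell (default 8e-5).
#' @param duplicates,runs Wells per count per run, and number of runs
#'   (defaults 2 and 3, i.e. n = 6 per count).
#' @return A list: `dataset`, `truth` (well, count, onset, steepest, x01,
#'   plateau) and `params` (`o0`, `ob`, `k`).
#' @export
generate_dilution_experiment <- function(cfg,
                                         seeded_counts = c(100000, 75000,
                                                           56250, 42188,
                                                           31641, 23731,
                                                           17798, 13348),
                                         o0 = 20, ob = 14, k = 8e-5,
                                         duplicates = 2L, runs = 3L) {
  stopifnot(inherits(cfg, "synth_config"))
  if (any(seeded_counts <= 0)) stop("seeded counts must be positive",
                                    call. = FALSE)
  set.seed(cfg$seed)
  t <- seq(0, cfg$duration, by = cfg$interval)
  grid <- expand.grid(rep = seq_len(duplicates * runs),
                      count = seeded_counts)
  onsets <- (o0 - ob) * exp(-k * grid$count) + ob
  wells <- sprintf("C%d.R%d", match(grid$count, seeded_counts), grid$rep)
  imp <- vapply(seq_len(nrow(grid)), function(i) {
    .synth_curve(t, cfg, onset = onsets[i]) +
      stats::rnorm(length(t), 0, cfg$noise_sd * cfg$amplitude)
  }, numeric(length(t)))
  truth <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    tr <- .synth_truth(cfg, onsets[i])
    data.frame(well = wells[i], count = grid$count[i], onset = tr$onset,
               steepest = tr$steepest, x01 = tr$x01, plateau = tr$plateau,
               stringsAsFactors = FALSE)
  }))
  list(dataset = ecis_dataset(t, imp, wells,
                              meta = list(source = "synthetic dilution",
                                          frequency_hz = 15000,
                                          seed = cfg$seed)),
       truth = truth, params = c(o0 = o0, ob = ob, k = k))
}

#' Generate a synthetic treatment experiment
#'
#' Emulates a treated-versus-control comparison: each treatment group's
#' growth onset is right-shifted by the configured hours (a toxic
#' treatment delays electrode coverage). The default layout is the pooled
#' five-runs-of-four-replicates design, i.e. 20 wells per group.
#'
#' @param cfg A [synth_config].
#' @param shifts Named numeric vector of onset shifts in hours per group;
#'   the first entry is the control and must be 0. Default
#'   `c(control = 0, low = 0, high = 2)`.
#' @param runs,wells_per_run Layout (defaults 5 and 4).
#' @return A list: `dataset`, `truth` (well, group, shift, onset) and
#'   `groups` (well -> group lookup).
#' @export
generate_treatment_experiment <- function(cfg,
                                          shifts = c(control = 0, low = 0,
                                                     high = 2),
                                          runs = 5L, wells_per_run = 4L) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(names(shifts)) || any(!nzchar(names(shifts))))
    stop("shifts must be named by group", call. = FALSE)
  if (shifts[1] != 0) stop("first group is the control; its shift must be 0",
                           call. = FALSE)
  n_rep <- runs * wells_per_run
  if (n_rep < 2L) stop("need at least 2 replicates per group",
                       call. = FALSE)
  set.seed(cfg$seed)
  t <- seq(0, cfg$duration, by = cfg$interval)
  lay <- expand.grid(rep = seq_len(n_rep), group = names(shifts),
                     stringsAsFactors = FALSE)
  onsets <- cfg$onset + shifts[lay$group]
  wells <- sprintf("%s.%d", lay$group, lay$rep)
  imp <- vapply(seq_len(nrow(lay)), function(i) {
    .synth_curve(t, cfg, onset = onsets[i]) +
      stats::rnorm(length(t), 0, cfg$noise_sd * cfg$amplitude)
  }, numeric(length(t)))
  truth <- data.frame(well = wells, group = lay$group,
                      shift = unname(shifts[lay$group]),
                      onset = unname(onsets), stringsAsFactors = FALSE)
  list(dataset = ecis_dataset(t, imp, wells,
                              meta = list(source = "synthetic treatment",
                                          frequency_hz = 15000,
                                          seed = cfg$seed)),
       truth = truth,
       groups = stats::setNames(lay$group, wells))
}
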