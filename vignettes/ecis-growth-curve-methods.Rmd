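---
title: "Modelling impedance-based growth curves: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling impedance-based growth curves: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecisgrowth)
```

## The measurement and the model problem

Electric cell-substrate impedance sensing (ECIS) records the electrical
impedance of gold electrodes embedded in the bottom of a cell-culture well.
As adherent cells attach, spread and proliferate, they progressively cover
the electrode and the impedance rises, producing a growth curve of
impedance (ohm) versus time (hours). A typical curve runs through five
chronological phases: a flat baseline, an exponential take-off, a roughly
linear growth phase, a saturating transition, and a plateau interpreted as
a confluent cell layer.

Group comparisons on such data (e.g. treated versus control wells) are far
more powerful when the whole trajectory is condensed into a small set of
curve reference points rather than a single timepoint. `ecisgrowth`
therefore fits, per well, three complementary curve models, extracts a
catalogue of reference points from each, and provides the downstream
trend-fitting and hypothesis-testing machinery.

## The three per-well curve models

**Cubic smoothing spline (`fit_spline`).** A penalized cubic spline through
the trace. The smoothness is selected by generalized cross-validation
(GCV); `spar` can be overridden. The spline is the model of choice for
irregular curves — oscillating plateaus, multi-wave growth — and supplies
continuous first and second derivatives. GCV was chosen because it is
fully automatic and parameter-free; the package does not attempt to guess
a "physiological" roughness.

**Four-parameter logistic (`fit_logistic4`).** The sigmoid
$f(x) = c + (d-c)/(1 + \exp(b(x-e)))$ with lower asymptote $c$, upper
asymptote $d$, slope parameter $b$ (1/h) and inflection time $e$ (h).
Under this parametrization an increasing growth curve carries $b < 0$. The
fit uses Levenberg–Marquardt least squares with automatic starting values:
$c_0 = \min y$, $d_0 = \max y$, $e_0$ at the empirical half-rise, and
$b_0 = -4/(t_{90} - t_{10})$ from the empirical 10%/90% crossings (this is
the exact slope-width relation of the logistic). If the first attempt
fails, sign-flipped and unit-slope restarts follow. Because the model is
symmetric under $(c,d,b) \to (d,c,-b)$, fitted parameters are
canonicalized to $c \le d$. Logistic asymptotes are poorly identified when
the baseline or plateau is short, which is why unit normalization
(`normalize_unit`) is recommended before logistic fitting; the
normalized flag in the dataset metadata is recognized automatically by the
batch fitter.

**Segmented (broken-line) regression (`fit_segmented`).** A continuous
piecewise-linear fit with `npsi` estimated knots. The knots are estimated
by the classic linearization of the broken-line model: refit with hinge
terms $(x - \psi_k)_+$ plus step terms $-I(x > \psi_k)$, and move each
knot by the step/hinge coefficient ratio $\gamma_k/\delta_k$. Updates are
damped by 0.5 and bounded by 20% of the time range per pass, iterated to
a tolerance of $10^{-4}\,\mathrm{range}(t)$ (at most 50 passes), then
polished with undamped full steps at $10^{-7}\,\mathrm{range}(t)$. Because
the iteration is only locally convergent, the fit is multi-started from
(i) knot quantiles of $t$, (ii) a uniform grid, and (iii) the best
$(npsi-1)$-knot solution with one extra knot inserted at each segment
midpoint; the lowest-RSS solution wins. Strategy (iii) also guarantees
that the residual sum of squares never increases when knots are added,
since the inserted-knot refit nests the smaller model. With `npsi = 3`
(the default) the knots typically separate baseline, growth and plateau;
3–10 knots work well for curves with largely linear subregions.

**Goodness of fit.** Every fit reports RMSE $=\sqrt{RSS/n}$, residual
variance $RV = RSS/(n-p)$, $R^2$, and the Gaussian maximum-likelihood AIC
$n\log(2\pi RSS/n) + n + 2(p+1)$. Both residual scalings are reported so
either convention can be compared against external software. For
numerically perfect fits the RSS is floored at $10^{-300}$ so the AIC
stays finite. Akaike weights $w_i \propto \exp(-\Delta_i/2)$ turn AIC
differences into normalized model support.

## Curve reference points

From the spline and logistic fits, `build_param_table` extracts the first
and second derivative maxima (FDM: fastest impedance change; SDM:
strongest acceleration, the take-off from the baseline) and the times of
10%, 20% and 50% of the fitted rise (`x01`, `x02`, `x05`). For the
logistic these have closed forms: $x_{FDM} = e$ with slope $-b(d-c)/4$,
$x_{SDM} = e + \log(2+\sqrt3)/b$, and $x_q = e + \log((1-q)/q)/b$. Spline
features are located by a deterministic 2000-point grid scan with local
refinement; the closed forms agree with the grid extraction to better
than $10^{-4}$ h (asserted in the tests). For the segmented model the
fractional-rise times are obtained by exact piecewise inversion and are
also exposed under the `p01/p02/p05` aliases, together with every knot,
segment slope and intercept and the fitted baseline level.

The "10% increase" levels are defined on the fitted amplitude: the
asymptote pair $(c, d)$ for the logistic, the min/max of fitted values for
the spline, and the end-segment levels for the segmented fit, with a
first-crossing-from-the-left rule on non-monotone fits. On
monotone-decreasing curves the derivative maxima are reported for the
absolute derivative and flagged with an orientation marker.

## Area under the curve

`integrate_simpson` implements the composite Simpson rule, exact up to
cubic polynomials on uniform grids with an even interval count.
Non-uniform or odd-count grids are linearly resampled onto the smallest
even interval count $\ge n-1$ (announced via a message, so resampling is
always on record). `auc_per_well` integrates each well, by default on
unit-normalized data over the full common time range — normalization makes
wells with different plateau impedance comparable; the alternatives are a
fixed end time or a per-well end at 99% of each well's own plateau level.

## Downstream statistics

For dilution-series calibrations, the time at which a curve reference
point is reached follows a saturating relation in the seeded cell count
$x$: `fit_exp_decay` fits $y = (y_0 - y_b)e^{-kx} + y_b$ and
`fit_exp_growth` fits the mirrored AUC relation
$y = y_{max}/(1+\exp(a+bx))$. `fit_polynomial` (degree 1–2) shares the
same AIC convention so linear/quadratic/saturating alternatives can be
ranked by Akaike weights. Confidence and prediction bands come from the
first-order delta method (gradient × parameter covariance), which is
deterministic and reproduces closed-form OLS intervals exactly on linear
fits; a bootstrap was deliberately not made the default to keep the
output seed-independent.

Group comparisons use Welch's unequal-variance *t*-test per
control-versus-treatment pair with Satterthwaite degrees of freedom, and
Bonferroni correction with the factor equal to the number of tested
pairs. Bonferroni (not Holm or BH) is the frozen default because with the
typical two or three pairs it is simple, conservative and familiar to the
field.

## The synthetic generator and what it does (not) show

`generate_growth_curves` integrates a smooth bell-shaped growth rate —
the product of two logistic gates, opening at the onset and closing
`growth_duration` later — which yields a $C^\infty$ five-phase curve that
is *not* itself a logistic, so spline-versus-logistic comparisons on
synthetic data are not rigged in favour of either parametric model.
Optional plateau drift and sinusoidal plateau oscillation create the
irregular shapes on which the spline is expected to win. Gaussian noise
is added as a fraction of the amplitude.

Default conditions: 6 wells (an 8-well dish minus two medium controls),
0.1 h sampling over 46.9 h, 500 ohm baseline, 1500 ohm amplitude, onset
at 10 h, gate rate 1.5/h, 6 h growth window, 1% noise. The dilution
generator shifts the onset by $onset(x) = (o_0-o_b)e^{-kx}+o_b$ with
defaults $o_0 = 20$ h, $o_b = 14$ h, $k = 8\times10^{-5}$ per cell across
the eight seeded counts 100000…13348 in 2 duplicates × 3 runs ($n = 6$
per count); the treatment generator right-shifts the onset per group in a
5-runs-of-4 layout (20 replicates per group), with a 2 h shift for the
"high" group and none for the "low" group by default. These magnitudes
were fixed once to sit in the range reported for epithelial dilution
experiments at 15 kHz and are not tuned afterwards.

Every generator returns the ground truth (onset, steepest point, 10% rise
time, plateau) computed on a 10× oversampled noiseless grid, so feature
extraction can always be tested against an oracle. What the generator
does **not** emulate: electrode micromotion, well-to-well baseline
heterogeneity, drift, or the multifactorial link between cell number and
impedance — passing tests demonstrate correctness of the numerics and the
pipeline plumbing, not biological validity on any particular cell line.

## Numerical choices and degenerate inputs

* Time grids must be strictly increasing and finite; blank cells in
  imports are an error by default, with optional linear imputation capped
  at 3 consecutive points (silent imputation hides instrument faults).
* Flat (constant) wells cannot be normalized or fitted; they produce a
  named error, or a `degenerate` status row in batch mode. Batch fitting
  never aborts on a single well — failures are statuses, not exceptions.
* Outlier wells are scored by the median-over-time of the pointwise
  robust z against the across-well median, with MAD guarded by
  $\varepsilon = 10^{-12}$; the default threshold is 3.5. Whole wells,
  never single timepoints, are flagged.
* Dataset combination interpolates onto the first grid when grids differ
  (within a 50%-overlap guard); ties and duplicate well ids are
  disambiguated by source-index suffixes.
* The leading-region editor prepends a flat prefix on the median sampling
  interval; this interpretation of "extension" is a documented package
  choice.
* All extraction scans are deterministic (fixed 2000-point grids,
  golden-section/`optimize` refinement); no step of the analysis pipeline
  consumes random numbers except the generators and any explicitly
  seeded simulation.

## Problem sizes used in validation

The shipped test-suite and the acceptance script run entirely on
synthetic data at the study layout: dilution 8 × 6 = 48 wells at 0.1 h
sampling over 46.9 h, treatment 3 × 20 = 60 wells over 30 h, 100-seed
parameter-recovery loops, and 2000 null simulations for the Welch
type-I calibration. These sizes keep each validation block in the
seconds-to-a-minute range on a single CPU while leaving the Monte-Carlo
margins (e.g. ±0.01 on a 0.05 rejection rate) comfortably inside the
asserted tolerances.

## Known limitations

* Only single-frequency tabular exports are modelled; no multi-frequency
  or equivalent-circuit modelling of the electrode.
* No five-parameter (asymmetric) logistic; strongly asymmetric sigmoids
  are better served by the spline.
* The segmented knot estimator is multi-started but still heuristic; for
  pathological curves the global optimum is not guaranteed.
* AUC-based potency summaries (e.g. IC50) are deliberately out of scope;
  the AUC is reported as a descriptive quantity only.
* No mixed-effects modelling of run/plate structure; replicates are
  pooled, as in the pipeline's intended two-group comparisons.
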