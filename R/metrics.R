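#' A gravimetric measurement
#'
#' Weight triple for one incubated sample: initial weight, wet weight after
#' blotting, and freeze-dried weight, all in the same unit (mg by
#' convention).
#'
#' @param w0 Initial sample weight (> 0).
#' @param ww Wet weight at the sampling time (>= wd).
#' @param wd Dry weight at the sampling time (> 0).
#' @param time Sampling time (any consistent unit; stored as given).
#' @return An object of class `gravimetric_sample`.
#' @export
gravimetric_sample <- function(w0, ww, wd, time = NA_real_) {
  stopifnot(is.numeric(w0), is.numeric(ww), is.numeric(wd),
            length(w0) == 1L, length(ww) == 1L, length(wd) == 1L)
  if (!is.finite(w0) || w0 <= 0) stop("'w0' must be positive")
  if (!is.finite(ww) || ww <= 0) stop("'ww' must be positive")
  if (!is.finite(wd) || wd <= 0) stop("'wd' must be positive")
  if (ww < wd) stop("wet weight must be at least the dry weight")
  structure(list(w0 = w0, ww = ww, wd = wd, time = time),
            class = "gravimetric_sample")
}

#' Percent mass loss of an incubated sample
#'
#' `(w0 - wd) / w0 * 100`: the fraction of the initial weight lost to the
#' medium by the sampling time, from the freeze-dried weight. A dry weight
#' above the initial weight (possible with noisy weighing of samples that
#' bound salts or water tightly) yields a negative loss, which is returned
#' with a warning rather than clipped.
#'
#' @param sample A [gravimetric_sample()].
#' @return Mass loss in percent.
#' @examples
#' mass_loss_percent(gravimetric_sample(w0 = 100, ww = 90, wd = 80))  # 20
#' @export
mass_loss_percent <- function(sample) {
  stopifnot(inherits(sample, "gravimetric_sample"))
  out <- (sample$w0 - sample$wd) / sample$w0 * 100
  if (out < 0)
    warning(sprintf(
      "dry weight exceeds initial weight: negative mass loss (%.3g%%)", out))
  out
}

#' Percent water uptake of an incubated sample
#'
#' `(ww - wd) / wd * 100`: water held by the sample relative to its dry
#' mass. Scale-invariant in the weights.
#'
#' @param sample A [gravimetric_sample()].
#' @return Water uptake in percent (>= 0 by the class invariant).
#' @examples
#' water_uptake_percent(gravimetric_sample(100, ww = 235.9, wd = 100))
#' @export
water_uptake_percent <- function(sample) {
  stopifnot(inherits(sample, "gravimetric_sample"))
  (sample$ww - sample$wd) / sample$wd * 100
}

#' A cumulative released-amount curve
#'
#' Cumulative amount of drug detected in the medium over time, in absolute
#' units (ng or ug), together with the loaded dose in the same unit.
#' Distinct from [release_curve()], which is normalised.
#'
#' @param times Strictly increasing non-negative times, s.
#' @param amounts Cumulative released amounts, non-negative.
#' @param dose Loaded dose, same unit as `amounts`.
#' @param unit Amount unit label (default "ng").
#' @return An object of class `cumulative_release`.
#' @export
cumulative_release <- function(times, amounts, dose, unit = "ng") {
  stopifnot(is.numeric(times), is.numeric(amounts),
            is.numeric(dose), length(dose) == 1L)
  if (length(times) != length(amounts))
    stop("'times' and 'amounts' must have equal length")
  if (any(!is.finite(times)) || any(times < 0) || any(diff(times) <= 0))
    stop("'times' must be non-negative and strictly increasing")
  if (any(!is.finite(amounts)) || any(amounts < 0))
    stop("'amounts' must be finite and non-negative")
  if (!is.finite(dose) || dose <= 0) stop("'dose' must be positive")
  structure(list(times = as.numeric(times), amounts = as.numeric(amounts),
                 dose = dose, unit = unit),
            class = "cumulative_release")
}

#' Burst fraction of a release profile
#'
#' Fraction of the loaded dose released within an initial window (24 h by
#' convention: the early disproportionately fast phase is what
#' formulations with a rate-controlling barrier are designed to damp).
#' The cumulative amount at the window boundary is obtained by linear
#' interpolation between the bracketing observations; when the window ends
#' exactly at an observation, that value is used as-is.
#'
#' @param curve A [cumulative_release()].
#' @param window Window length, s (default 24 h).
#' @return Fraction of dose in \[0, 1\] (can exceed 1 only if measured
#'   amounts exceed the nominal dose).
#' @examples
#' cv <- cumulative_release(c(3600, 86400, 7 * 86400), c(50, 270, 400),
#'                          dose = 1000)
#' burst_fraction(cv)   # 0.27
#' @export
burst_fraction <- function(curve, window = 86400) {
  stopifnot(inherits(curve, "cumulative_release"),
            is.numeric(window), length(window) == 1L, window > 0)
  if (curve$times[1] > window)
    stop("no observation at or before the burst window")
  if (window > max(curve$times))
    stop("burst window extends beyond the last observation")
  amount <- stats::approx(curve$times, curve$amounts, xout = window,
                          ties = "ordered")$y
  amount / curve$dose
}

#' Release rate over a time window
#'
#' Least-squares slope of cumulative amount versus time over
#' `[t_start, t_end]`, reported per day. This is the descriptive statistic
#' used to summarise the sustained phase of a biphasic profile (e.g. a
#' second phase maintained at tens of ng/day over weeks).
#'
#' @param curve A [cumulative_release()].
#' @param t_start,t_end Window bounds, s.
#' @return Slope in amount units per day.
#' @export
phase_rate <- function(curve, t_start, t_end) {
  stopifnot(inherits(curve, "cumulative_release"),
            is.numeric(t_start), is.numeric(t_end), t_start < t_end)
  sel <- curve$times >= t_start & curve$times <= t_end
  if (sum(sel) < 2L)
    stop("need at least 2 observations inside the window")
  fit <- stats::lm.fit(cbind(1, curve$times[sel]),
                       curve$amounts[sel])
  unname(fit$coefficients[2] * 86400)
}
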