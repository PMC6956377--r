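#' Define a synthetic release scenario
#'
#' A scenario is a named set of study conditions: the true physical
#' parameters, a sampling-time design, an additive noise level on the
#' fraction scale, a replicate count and a seed. Scenarios drive the
#' package's validation machinery: curves generated from a scenario carry
#' their generating truth so parameter recovery can be checked.
#'
#' @param name Scenario label.
#' @param true_params A [model_params()] object.
#' @param noise_sd Standard deviation of additive Gaussian noise on the
#'   fraction scale (values are truncated back to \[0, 1\]). Default 0.02,
#'   a typical spectrophotometric readout error on normalised data.
#' @param n_replicates Number of replicate curves.
#' @param seed RNG seed.
#' @param time_design Either a numeric vector of times (s), or a list
#'   `list(n, f_lo, f_hi)` requesting `n` log-spaced times between the
#'   times at which the noiseless model reaches fractions `f_lo` and
#'   `f_hi`. The default (12 points spanning 0.05 to 0.99) covers both the
#'   early boundary-layer-sensitive and the late diffusion-sensitive parts
#'   of the curve, which is what identifiability of (D_eff, h) requires.
#' @return An object of class `release_scenario`.
#' @export
release_scenario <- function(name, true_params, noise_sd = 0.02,
                             n_replicates = 3L, seed = 1L,
                             time_design = list(n = 12L, f_lo = 0.05,
                                                f_hi = 0.99)) {
  stopifnot(inherits(true_params, "model_params"),
            is.numeric(noise_sd), length(noise_sd) == 1L, noise_sd >= 0,
            is.numeric(seed), length(seed) == 1L)
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 1L) stop("'n_replicates' must be positive")
  if (is.numeric(time_design)) {
    if (length(time_design) < 3L)
      stop("a time design must provide at least 3 points")
    if (any(diff(time_design) <= 0))
      stop("explicit times must be strictly increasing")
  } else if (is.list(time_design)) {
    if (is.null(time_design$n) || time_design$n < 3L)
      stop("a time design must provide at least 3 points")
    stopifnot(time_design$f_lo > 0, time_design$f_hi < 1,
              time_design$f_lo < time_design$f_hi)
  } else stop("'time_design' must be a numeric vector or a design list")
  structure(list(name = name, true_params = true_params,
                 noise_sd = noise_sd, n_replicates = n_replicates,
                 seed = as.integer(seed), time_design = time_design),
            class = "release_scenario")
}

#' @export
print.release_scenario <- function(x, ...) {
  cat(sprintf("Release scenario '%s'\n", x$name))
  cat(sprintf("  D_eff %.3g m^2/s, h %.3g m/s, R %.3g m (Biot L = %.3g)\n",
              x$true_params$d_eff, x$true_params$h, x$true_params$radius,
              biot_number(x$true_params)))
  cat(sprintf("  noise sd %.3g, %d replicate(s), seed %d\n",
              x$noise_sd, x$n_replicates, x$seed))
  invisible(x)
}

# resolve a scenario's time design to explicit times in seconds
.design_times <- function(scenario) {
  td <- scenario$time_design
  if (is.numeric(td)) return(as.numeric(td))
  t_lo <- time_at_fraction(scenario$true_params, td$f_lo)
  t_hi <- time_at_fraction(scenario$true_params, td$f_hi)
  exp(seq(log(t_lo), log(t_hi), length.out = td$n))
}

#' Generate replicate release curves from a scenario
#'
#' Evaluates the finite-Biot release series at the scenario's design times
#' and adds independent Gaussian noise per replicate, truncating to
#' \[0, 1\]. Reproducible: the same scenario (including seed) always yields
#' the same data. The generating truth is attached to each curve as
#' attribute `"true_params"`.
#'
#' @param scenario A [release_scenario()].
#' @return List of [release_curve()] objects, one per replicate.
#' @examples
#' curves <- simulate_release_curves(builtin_scenarios()$sls_aqueous)
#' length(curves)
#' @export
simulate_release_curves <- function(scenario) {
  stopifnot(inherits(scenario, "release_scenario"))
  times <- .design_times(scenario)
  if (length(times) < 3L) stop("time design produced fewer than 3 points")
  clean <- fractional_release(scenario$true_params, times, quiet = TRUE)
  .with_seed(scenario$seed, {
    lapply(seq_len(scenario$n_replicates), function(i) {
      noisy <- clean + stats::rnorm(length(times), sd = scenario$noise_sd)
      cv <- release_curve(times, pmin(pmax(noisy, 0), 1),
                          replicate_id = sprintf("%s_rep%d", scenario$name, i))
      attr(cv, "true_params") <- scenario$true_params
      cv
    })
  })
}

#' Built-in validation scenarios
#'
#' Three reference regimes for validation studies, all at the default
#' 50.7 um radius:
#' \describe{
#'   \item{`meoh_water`}{fast medium (methanol:water 50:50):
#'     D_eff = 2.28e-15 m^2/s, h = 7.56e-10 m/s (Biot about 17).}
#'   \item{`sls_aqueous`}{slow aqueous surfactant medium (1% SLS):
#'     D_eff = 5.58e-16 m^2/s, h = 4.01e-10 m/s (Biot about 36).}
#'   \item{`low_biot`}{boundary-layer-controlled regime at Biot = 1
#'     (same D_eff as the aqueous medium, h reduced accordingly), for
#'     exercising h-identifiability diagnostics.}
#' }
#'
#' @param noise_sd,n_replicates,seed Passed to every scenario.
#' @return Named list of [release_scenario()] objects.
#' @export
builtin_scenarios <- function(noise_sd = 0.02, n_replicates = 3L,
                              seed = 1L) {
  R <- default_radius()
  list(
    meoh_water = release_scenario(
      "meoh_water",
      model_params(d_eff = 2.28e-15, h = 7.56e-10, radius = R),
      noise_sd = noise_sd, n_replicates = n_replicates, seed = seed),
    sls_aqueous = release_scenario(
      "sls_aqueous",
      model_params(d_eff = 5.58e-16, h = 4.01e-10, radius = R),
      noise_sd = noise_sd, n_replicates = n_replicates, seed = seed),
    low_biot = release_scenario(
      "low_biot",
      model_params(d_eff = 5.58e-16, h = 1 * 5.58e-16 / R, radius = R),
      noise_sd = noise_sd, n_replicates = n_replicates, seed = seed)
  )
}

#' Generate a synthetic gravimetric weight series
#'
#' Constructs (initial, wet, dry) weight triples whose noiseless mass-loss
#' and water-uptake percentages equal the supplied profiles, then applies
#' multiplicative Gaussian noise to the measured wet and dry weights.
#' Useful for round-trip testing of [mass_loss_percent()] and
#' [water_uptake_percent()].
#'
#' @param w0 Initial sample weight, mg.
#' @param times Measurement times, s (or any consistent unit; stored as
#'   given).
#' @param loss_pct Expected mass-loss percentages at `times` (0-100).
#' @param uptake_pct Expected water-uptake percentages at `times` (>= 0).
#' @param noise_sd Relative standard deviation of weight measurement noise.
#' @param seed RNG seed.
#' @return List of [gravimetric_sample()] objects.
#' @export
simulate_gravimetric_series <- function(w0, times, loss_pct, uptake_pct,
                                        noise_sd = 0, seed = 1L) {
  stopifnot(is.numeric(w0), length(w0) == 1L, w0 > 0,
            is.numeric(times), is.numeric(loss_pct), is.numeric(uptake_pct),
            length(times) == length(loss_pct),
            length(times) == length(uptake_pct),
            noise_sd >= 0)
  if (any(loss_pct < 0) || any(loss_pct >= 100))
    stop("'loss_pct' must lie in [0, 100): the dry weight cannot exceed w0")
  if (any(uptake_pct < 0))
    stop("'uptake_pct' must be non-negative: wet weight cannot be below dry")
  .with_seed(seed, {
    lapply(seq_along(times), function(i) {
      wd <- w0 * (1 - loss_pct[i] / 100)
      ww <- wd * (1 + uptake_pct[i] / 100)
      if (noise_sd > 0) {
        wd <- wd * (1 + stats::rnorm(1, sd = noise_sd))
        ww <- ww * (1 + stats::rnorm(1, sd = noise_sd))
        wd <- max(wd, w0 * 1e-6)
        ww <- max(ww, wd)   # keep the wet >= dry invariant under noise
      }
      gravimetric_sample(w0 = w0, ww = ww, wd = wd, time = times[i])
    })
  })
}
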