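#' Fitting configuration
#'
#' Settings for [fit_release()]. The search runs in log10 space because the
#' physically plausible ranges of the two parameters span many decades
#' (diffusivities around 1e-16 m^2/s, mass-transfer coefficients around
#' 1e-10 m/s). The optimizer is a genetic algorithm (tournament selection,
#' uniform crossover, Gaussian mutation in log space, elitism of one),
#' optionally followed by a derivative-free simplex polish.
#'
#' @param log10_d_eff_bounds Search bounds for log10(D_eff / (m^2/s)).
#' @param log10_h_bounds Search bounds for log10(h / (m/s)).
#' @param population_size GA population size (>= 4).
#' @param generations Number of GA generations.
#' @param crossover_rate Probability a selected parent pair is recombined.
#' @param mutation_rate Per-gene probability of Gaussian mutation.
#' @param seed RNG seed recorded in every result; identical seed and inputs
#'   give identical fits.
#' @param polish Run a Nelder-Mead refinement from the GA optimum. The GA
#'   alone rarely resolves the optimum beyond ~1e-3 relative.
#' @param model_variant `"full"` for the finite-Biot eigenvalue series,
#'   `"simplified"` for the diffusion-controlled limit (which does not
#'   involve h, so only D_eff is estimated), or `"auto"` to use the limit
#'   series whenever the candidate Biot number is at least
#'   `large_l_threshold`.
#' @param large_l_threshold Biot number above which `"auto"` switches to the
#'   limit series; at 1e3 the first eigenvalue differs from pi by under
#'   1e-3 relative.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(log10_d_eff_bounds = c(-20, -10),
                       log10_h_bounds = c(-14, -6),
                       population_size = 60L,
                       generations = 200L,
                       crossover_rate = 0.7,
                       mutation_rate = 0.2,
                       seed = 1L,
                       polish = TRUE,
                       model_variant = c("auto", "full", "simplified"),
                       large_l_threshold = 1e3) {
  model_variant <- match.arg(model_variant)
  chk_bounds <- function(b, nm) {
    if (!is.numeric(b) || length(b) != 2L || any(!is.finite(b)) ||
        b[1] >= b[2])
      stop(sprintf("'%s' must be finite bounds with lower < upper", nm))
  }
  chk_bounds(log10_d_eff_bounds, "log10_d_eff_bounds")
  chk_bounds(log10_h_bounds, "log10_h_bounds")
  population_size <- as.integer(population_size)
  generations <- as.integer(generations)
  if (population_size < 4L) stop("'population_size' must be at least 4")
  if (generations < 1L) stop("'generations' must be positive")
  stopifnot(crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.logical(polish), length(polish) == 1L,
            is.numeric(large_l_threshold), large_l_threshold > 0)
  structure(list(log10_d_eff_bounds = as.numeric(log10_d_eff_bounds),
                 log10_h_bounds = as.numeric(log10_h_bounds),
                 population_size = population_size,
                 generations = generations,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 seed = as.integer(seed),
                 polish = polish,
                 model_variant = model_variant,
                 large_l_threshold = large_l_threshold),
            class = "fit_config")
}

#' Residual sum of squares of a release curve under given parameters
#'
#' @param curve A [release_curve()] with at least 3 points.
#' @param params A [model_params()] object.
#' @param model_variant Series variant, as in [fit_config()].
#' @param large_l_threshold Dispatch threshold for `"auto"`.
#' @return Sum of squared observed-minus-predicted fractions.
#' @export
residual_sum_of_squares <- function(curve, params, model_variant = "auto",
                                    large_l_threshold = 1e3) {
  stopifnot(inherits(curve, "release_curve"),
            inherits(params, "model_params"))
  if (length(curve$times) < 3L)
    stop("need at least 3 observations to assess a fit")
  pred <- .predict_release(params, curve$times, model_variant,
                           large_l_threshold)
  sum((curve$fractions - pred)^2)
}

#' Coefficient of determination, in percent
#'
#' `100 * (1 - SS_res / SS_tot)`, the conventional R^2 scaled to percent as
#' release-kinetics tables report it. Can be negative for fits worse than
#' the mean.
#'
#' @inheritParams residual_sum_of_squares
#' @return R^2 in percent (<= 100).
#' @export
r_squared <- function(curve, params, model_variant = "auto",
                      large_l_threshold = 1e3) {
  stopifnot(inherits(curve, "release_curve"))
  if (length(curve$times) < 3L)
    stop("need at least 3 observations to assess a fit")
  ss_tot <- sum((curve$fractions - mean(curve$fractions))^2)
  if (ss_tot == 0)
    stop("observations have zero variance; R^2 is undefined")
  ss_res <- residual_sum_of_squares(curve, params, model_variant,
                                    large_l_threshold)
  100 * (1 - ss_res / ss_tot)
}

# run code under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Genetic algorithm minimiser on a box. Tournament selection (size 3),
# uniform crossover, per-gene Gaussian mutation (sd = 10% of range),
# elitism of one. Returns the best point found. Caller seeds the RNG.
.ga_minimize <- function(obj, lower, upper, population_size, generations,
                         crossover_rate, mutation_rate) {
  d <- length(lower)
  range <- upper - lower
  pop <- matrix(stats::runif(population_size * d), population_size, d)
  pop <- sweep(sweep(pop, 2, range, "*"), 2, lower, "+")
  fit <- apply(pop, 1, obj)

  tournament <- function() {
    idx <- sample.int(population_size, 3L)
    idx[which.min(fit[idx])]
  }
  for (g in seq_len(generations)) {
    elite_i <- which.min(fit)
    new_pop <- matrix(NA_real_, population_size, d)
    new_pop[1, ] <- pop[elite_i, ]
    i <- 2L
    while (i <= population_size) {
      p1 <- pop[tournament(), ]
      p2 <- pop[tournament(), ]
      if (stats::runif(1) < crossover_rate) {
        mask <- stats::runif(d) < 0.5
        c1 <- ifelse(mask, p1, p2)
        c2 <- ifelse(mask, p2, p1)
      } else {
        c1 <- p1; c2 <- p2
      }
      for (child in list(c1, c2)) {
        if (i > population_size) break
        mut <- stats::runif(d) < mutation_rate
        child[mut] <- child[mut] +
          stats::rnorm(sum(mut), sd = 0.1 * range[mut])
        new_pop[i, ] <- pmin(pmax(child, lower), upper)
        i <- i + 1L
      }
    }
    pop <- new_pop
    fit <- c(fit[elite_i], apply(pop[-1, , drop = FALSE], 1, obj))
  }
  best <- which.min(fit)
  list(par = pop[best, ], value = fit[best])
}

#' Fit the sphere release model to a cumulative release curve
#'
#' Estimates the effective diffusion coefficient D_eff and the
#' boundary-layer mass-transfer coefficient h of the diffusion-with-
#' boundary-layer release model by minimising the residual sum of squares
#' between observed and model fractional release. The search runs in log10
#' space with a seeded genetic algorithm followed (by default) by
#' Nelder-Mead refinement.
#'
#' With `model_variant = "simplified"` the diffusion-controlled limit
#' series is fitted; it does not involve h, so only D_eff is estimated and
#' h is reported as `NA`.
#'
#' The result carries two diagnostics an honest report needs: whether any
#' estimate sits at a search bound, and whether h is *weakly identified* --
#' i.e. doubling or halving h at the optimum changes the RSS by less than
#' `max(1e-3 * RSS, 1e-12)`, in which case the data cannot pin h down and
#' its point value should not be over-read. This situation is expected
#' whenever release is diffusion-controlled (large Biot number).
#'
#' @param x A [release_curve()], or a formula `fraction ~ time` (times in
#'   seconds) evaluated in `data`.
#' @param radius Sphere radius in metres; fixed, not estimated.
#' @param config A [fit_config()].
#' @param ... Passed between methods.
#' @return An object of class `release_fit` with components `params`
#'   ([model_params()] with the estimates), `rss`, `r_squared` (percent),
#'   `n_points`, `model_variant` (requested), `variant_used` (series active
#'   at the optimum), `seed`, `converged`, `h_weakly_identified`,
#'   `at_bound`, `fitted`, `residuals`, `curve`, `config`.
#' @seealso [fit_replicates()] for replicate aggregation;
#'   [residual_sum_of_squares()], [r_squared()].
#' @examples
#' \donttest{
#' sc <- builtin_scenarios()$sls_aqueous
#' sc$noise_sd <- 0; sc$n_replicates <- 1L
#' curve <- simulate_release_curves(sc)[[1]]
#' cfg <- fit_config(generations = 40, population_size = 30)
#' fit <- fit_release(curve, radius = sc$true_params$radius, config = cfg)
#' coef(fit)
#' }
#' @export
fit_release <- function(x, ...) UseMethod("fit_release")

#' @rdname fit_release
#' @param data Data frame in which a formula `x` is evaluated.
#' @export
fit_release.formula <- function(x, data, radius = default_radius(),
                                config = fit_config(), ...) {
  mf <- stats::model.frame(x, data)
  if (ncol(mf) != 2L)
    stop("formula must have the form fraction ~ time")
  curve <- release_curve(times = mf[[2L]], fractions = mf[[1L]])
  fit_release(curve, radius = radius, config = config, ...)
}

#' @rdname fit_release
#' @export
fit_release.release_curve <- function(x, radius = default_radius(),
                                      config = fit_config(), ...) {
  stopifnot(inherits(config, "fit_config"),
            is.numeric(radius), length(radius) == 1L, radius > 0)
  curve <- x
  if (length(curve$times) < 3L)
    stop("need at least 3 observations to fit the release model")
  if (any(!is.finite(curve$fractions)))
    stop("release curve contains non-finite fractions; cannot fit")
  if (stats::sd(curve$fractions) == 0)
    stop("release curve is constant; cannot fit")

  variant <- config$model_variant
  thr <- config$large_l_threshold
  simplified_only <- variant == "simplified"

  make_params <- function(theta) {
    if (simplified_only)
      model_params(10^theta[1], h = 1, radius = radius)  # h unused
    else
      model_params(10^theta[1], 10^theta[2], radius = radius)
  }
  obj <- function(theta)
    sum((curve$fractions -
           .predict_release(make_params(theta), curve$times,
                            if (simplified_only) "simplified" else variant,
                            thr))^2)

  lower <- config$log10_d_eff_bounds[1]
  upper <- config$log10_d_eff_bounds[2]
  if (!simplified_only) {
    lower <- c(lower, config$log10_h_bounds[1])
    upper <- c(upper, config$log10_h_bounds[2])
  }

  ga <- .with_seed(config$seed,
                   .ga_minimize(obj, lower, upper,
                                config$population_size, config$generations,
                                config$crossover_rate, config$mutation_rate))
  par <- ga$par
  rss <- ga$value
  converged <- TRUE
  if (config$polish) {
    if (length(par) == 1L) {
      op <- stats::optim(par, obj, method = "Brent",
                         lower = lower, upper = upper)
    } else {
      op <- stats::optim(par, obj, method = "Nelder-Mead",
                         control = list(maxit = 1000, reltol = 1e-14))
    }
    if (op$value <= rss) {
      par <- pmin(pmax(op$par, lower), upper)
      rss <- obj(par)
    }
    converged <- op$convergence == 0L
  }

  params <- make_params(par)
  if (simplified_only) params$h <- NA_real_

  at_bound <- abs(par - lower) < 1e-6 * (upper - lower) |
    abs(par - upper) < 1e-6 * (upper - lower)
  names(at_bound) <- if (simplified_only) "log10_d_eff"
                     else c("log10_d_eff", "log10_h")

  if (simplified_only) {
    h_weak <- NA
  } else {
    d_up <- abs(obj(par + c(0, log10(2))) - rss)
    d_dn <- abs(obj(par - c(0, log10(2))) - rss)
    h_weak <- max(d_up, d_dn) < max(1e-3 * rss, 1e-12)
  }

  pred_variant <- if (simplified_only) "simplified" else variant
  fitted_vals <- .predict_release(
    if (simplified_only) model_params(params$d_eff, 1, radius) else params,
    curve$times, pred_variant, thr)
  variant_used <- if (simplified_only) "simplified"
    else if (variant == "full") "full"
    else if (biot_number(params) >= thr) "simplified" else "full"

  ss_tot <- sum((curve$fractions - mean(curve$fractions))^2)
  structure(list(params = params,
                 radius = radius,
                 rss = rss,
                 r_squared = 100 * (1 - rss / ss_tot),
                 n_points = length(curve$times),
                 model_variant = variant,
                 variant_used = variant_used,
                 seed = config$seed,
                 converged = converged,
                 h_weakly_identified = h_weak,
                 at_bound = at_bound,
                 fitted = fitted_vals,
                 residuals = curve$fractions - fitted_vals,
                 curve = curve,
                 config = config),
            class = "release_fit")
}

#' @export
print.release_fit <- function(x, ...) {
  cat("Sphere release model fit\n")
  cat(sprintf("  D_eff    : %.4g m^2/s\n", x$params$d_eff))
  if (is.na(x$params$h)) {
    cat("  h        : not estimable (diffusion-controlled limit fitted)\n")
  } else {
    cat(sprintf("  h        : %.4g m/s%s\n", x$params$h,
                if (isTRUE(x$h_weakly_identified))
                  "  [weakly identified]" else ""))
    cat(sprintf("  Biot L   : %.4g\n", biot_number(x$params)))
  }
  cat(sprintf("  R        : %.4g m (fixed)\n", x$radius))
  cat(sprintf("  RSS      : %.4g on %d points\n", x$rss, x$n_points))
  cat(sprintf("  R^2      : %.2f %%\n", x$r_squared))
  if (any(x$at_bound))
    cat("  warning  : estimate at search bound:",
        paste(names(x$at_bound)[x$at_bound], collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.release_fit <- function(object, ...) {
  c(d_eff = object$params$d_eff, h = object$params$h)
}

#' @export
fitted.release_fit <- function(object, ...) object$fitted

#' @export
residuals.release_fit <- function(object, ...) object$residuals

#' @export
deviance.release_fit <- function(object, ...) object$rss

#' @export
predict.release_fit <- function(object, newdata = NULL, ...) {
  times <- if (is.null(newdata)) object$curve$times
           else if (is.data.frame(newdata)) newdata$time
           else newdata
  p <- object$params
  if (is.na(p$h)) p <- model_params(p$d_eff, 1, object$radius)
  .predict_release(p, times,
                   if (object$variant_used == "simplified") "simplified"
                   else "full",
                   object$config$large_l_threshold)
}

#' @export
summary.release_fit <- function(object, ...) {
  structure(list(fit = object,
                 sigma = sqrt(object$rss /
                                max(object$n_points - 2L, 1L))),
            class = "summary.release_fit")
}

#' @export
print.summary.release_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  residual sd : %.4g (df = %d)\n", x$sigma,
              max(f$n_points - 2L, 1L)))
  cat(sprintf("  variant     : requested '%s', used '%s'\n",
              f$model_variant, f$variant_used))
  cat(sprintf("  seed        : %d; converged: %s\n", f$seed, f$converged))
  qr <- stats::quantile(f$residuals)
  cat("  residual quartiles:",
      paste(sprintf("%.3g", qr), collapse = "  "), "\n")
  invisible(x)
}

#' @export
plot.release_fit <- function(x, n_grid = 200, time_unit = c("day", "h", "s"),
                             ...) {
  time_unit <- match.arg(time_unit)
  div <- c(day = 86400, h = 3600, s = 1)[[time_unit]]
  tt <- seq(0, max(x$curve$times), length.out = n_grid)
  pred <- predict(x, tt)
  graphics::plot(x$curve$times / div, x$curve$fractions,
                 xlab = sprintf("time (%s)", time_unit),
                 ylab = "cumulative fractional release",
                 ylim = c(0, 1.02), ...)
  graphics::lines(tt / div, pred)
  invisible(x)
}

#' @export
simulate.release_fit <- function(object, nsim = 1, seed = NULL, ...) {
  sigma <- sqrt(object$rss / max(object$n_points - 2L, 1L))
  sim <- function() {
    f <- pmin(pmax(object$fitted +
                     stats::rnorm(object$n_points, sd = sigma), 0), 1)
    release_curve(object$curve$times, f,
                  replicate_id = "sim",
                  normalization_mode = object$curve$normalization_mode)
  }
  out <- if (is.null(seed)) replicate(nsim, sim(), simplify = FALSE)
         else .with_seed(seed, replicate(nsim, sim(), simplify = FALSE))
  if (nsim == 1L) out[[1L]] else out
}

#' Fit replicate release curves and aggregate the estimates
#'
#' Fits each replicate independently (the RNG seed is offset by the
#' replicate index so replicates explore different GA trajectories) and
#' reports mean and sample standard deviation of D_eff, h and R^2 across
#' replicates, the reporting style of release-kinetics tables. Replicates
#' that cannot be fitted are excluded and flagged rather than failing the
#' whole set.
#'
#' @param curves List of [release_curve()] objects from one condition.
#' @param radius Sphere radius, m.
#' @param config A [fit_config()].
#' @return An object of class `replicate_summary`: list with `fits`,
#'   `n_replicates`, `excluded` (character vector of replicate ids),
#'   `d_eff`, `h`, `r_squared` (each a c(mean, sd) vector; sd is `NA` and
#'   flagged when fewer than 2 replicates were fitted), and
#'   `h_weak_fraction` (share of fits with weakly identified h).
#' @export
fit_replicates <- function(curves, radius = default_radius(),
                           config = fit_config()) {
  stopifnot(is.list(curves), length(curves) >= 1L)
  fits <- list()
  excluded <- character()
  for (i in seq_along(curves)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + (i - 1L)
    res <- tryCatch(fit_release(curves[[i]], radius = radius, config = cfg_i),
                    error = function(e) e)
    if (inherits(res, "error")) {
      excluded <- c(excluded, curves[[i]]$replicate_id)
      warning(sprintf("replicate '%s' could not be fitted: %s",
                      curves[[i]]$replicate_id, conditionMessage(res)))
    } else {
      fits[[length(fits) + 1L]] <- res
    }
  }
  if (length(fits) == 0L) stop("no replicate could be fitted")
  agg <- function(v) {
    m <- mean(v)
    s <- if (length(v) >= 2L) stats::sd(v) else NA_real_
    c(mean = m, sd = s)
  }
  d <- vapply(fits, function(f) f$params$d_eff, numeric(1))
  h <- vapply(fits, function(f) f$params$h, numeric(1))
  r2 <- vapply(fits, function(f) f$r_squared, numeric(1))
  weak <- vapply(fits, function(f) isTRUE(f$h_weakly_identified), logical(1))
  structure(list(fits = fits,
                 n_replicates = length(fits),
                 excluded = excluded,
                 d_eff = agg(d),
                 h = agg(h),
                 r_squared = agg(r2),
                 h_weak_fraction = mean(weak),
                 sd_defined = length(fits) >= 2L),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  fmt <- function(v, unit) {
    if (is.na(v["sd"]))
      sprintf("%.4g %s (SD undefined: single replicate)", v["mean"], unit)
    else sprintf("%.4g +/- %.3g %s", v["mean"], v["sd"], unit)
  }
  cat(sprintf("Replicate release fits (n = %d%s)\n", x$n_replicates,
              if (length(x$excluded))
                sprintf(", %d excluded: %s", length(x$excluded),
                        paste(x$excluded, collapse = ", ")) else ""))
  cat("  D_eff :", fmt(x$d_eff, "m^2/s"), "\n")
  cat("  h     :", fmt(x$h, "m/s"), "\n")
  cat("  R^2   :", fmt(x$r_squared, "%"), "\n")
  if (x$h_weak_fraction > 0)
    cat(sprintf("  h weakly identified in %.0f%% of fits\n",
                100 * x$h_weak_fraction))
  invisible(x)
}
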