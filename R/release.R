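# Series evaluation of the sphere release model.
#
# Both series share the same structure 1 - sum(c_n * exp(-beta_n^2 * tau))
# with tau = D_eff * t / R^2 the dimensionless time. Truncation is adaptive:
# terms are added until the next term magnitude at the smallest requested tau
# falls below 1e-10 AND a geometric tail bound falls below 1e-8, with a hard
# cap of 10^4 terms. Below tau = 1e-6 the series converges too slowly to be
# worth summing and the release is physically negligible; those points are
# returned as 0 (with a note unless quiet).

.series_cap <- 10000L
.series_term_tol <- 1e-10
.series_tail_tol <- 1e-8
.tau_floor <- 1e-6

# coefficients and squared eigenvalues of the exact (finite-L) series
.series_terms_exact <- function(biot, n) {
  beta <- solve_eigenvalues(biot, n, tol = 1e-8)$roots
  b2 <- beta^2
  list(coef = 6 * biot^2 / (b2 * (b2 + biot^2 - biot)), beta2 = b2)
}

# coefficients of the diffusion-controlled limit: beta_n = n*pi
.series_terms_large_l <- function(n) {
  k <- seq_len(n)
  list(coef = 6 / (pi^2 * k^2), beta2 = (k * pi)^2)
}

# choose the truncation order for a given smallest tau, then evaluate
.series_sum <- function(terms_fun, tau) {
  pos <- tau >= .tau_floor
  out <- numeric(length(tau))
  if (!any(pos)) return(out)
  tau_min <- min(tau[pos])

  n <- 32L
  repeat {
    tm <- terms_fun(n)
    last <- tm$coef[n] * exp(-tm$beta2[n] * tau_min)
    r <- exp(-(tm$beta2[n] - tm$beta2[n - 1L]) * tau_min)
    tail_bound <- if (r < 1) last * r / (1 - r) else Inf
    if ((last < .series_term_tol && tail_bound < .series_tail_tol) ||
        n >= .series_cap) break
    n <- min(2L * n, .series_cap)
  }
  s <- vapply(tau[pos],
              function(tt) sum(tm$coef * exp(-tm$beta2 * tt)),
              numeric(1))
  out[pos] <- pmin(pmax(1 - s, 0), 1)
  out
}

#' Fractional release from a sphere with boundary-layer resistance
#'
#' Evaluates the cumulative fractional release M_t / M_inf of a drug
#' diffusing out of a sphere of radius R with effective diffusivity D_eff,
#' through an external boundary layer with mass-transfer coefficient h:
#' \deqn{M_t/M_\infty = 1 - \sum_{n\ge1} \frac{6L^2}{\beta_n^2(\beta_n^2+L^2-L)}
#'   \exp(-\beta_n^2 D_{eff} t / R^2)}
#' where L = hR/D_eff is the Biot number and beta_n the roots returned by
#' [solve_eigenvalues()]. The series is truncated adaptively (see Details).
#'
#' @details Terms are added until the next term is below 1e-10 and a
#' geometric tail bound is below 1e-8, capped at 10^4 terms. Times with
#' dimensionless tau = D_eff*t/R^2 below 1e-6 are returned as 0 (release is
#' negligible and the series converges very slowly there); a note is emitted
#' unless `quiet = TRUE`. For Biot numbers of 1e8 and above the finite-L
#' coefficients agree with the diffusion-controlled limit to well below the
#' truncation tolerance and the limit series is used.
#'
#' @param params A [model_params()] object.
#' @param times Non-negative times, s.
#' @param quiet Suppress the small-time note.
#' @return Numeric vector of fractions in \[0, 1\], non-decreasing with time.
#' @seealso [fractional_release_large_l()], [release_profile_tau()]
#' @examples
#' p <- model_params(d_eff = 5.58e-16, h = 4.01e-10, radius = 50.7e-6)
#' fractional_release(p, c(0, 1, 7, 28) * 86400)
#' @export
fractional_release <- function(params, times, quiet = FALSE) {
  stopifnot(inherits(params, "model_params"), is.numeric(times))
  if (any(!is.finite(times)) || any(times < 0))
    stop("'times' must be finite and non-negative")
  tau <- params$d_eff * times / params$radius^2
  small <- times > 0 & tau < .tau_floor
  if (any(small) && !quiet)
    message(sprintf(
      "%d time point(s) below dimensionless time %g returned as 0",
      sum(small), .tau_floor))
  L <- biot_number(params)
  if (L >= 1e8) return(.series_sum(.series_terms_large_l, tau))
  .series_sum(function(n) .series_terms_exact(L, n), tau)
}

#' Fractional release in the diffusion-controlled (large Biot) limit
#'
#' The simplification of the sphere release series for large Biot number,
#' where the eigenvalues become multiples of pi:
#' \deqn{M_t/M_\infty = 1 - \frac{6}{\pi^2}\sum_{n\ge1} \frac{1}{n^2}
#'   \exp(-n^2\pi^2 D_{eff} t / R^2).}
#' The boundary layer drops out entirely, so the result depends on `params`
#' only through D_eff and R.
#'
#' @inheritParams fractional_release
#' @return Numeric vector of fractions in \[0, 1\].
#' @export
fractional_release_large_l <- function(params, times, quiet = FALSE) {
  stopifnot(inherits(params, "model_params"), is.numeric(times))
  if (any(!is.finite(times)) || any(times < 0))
    stop("'times' must be finite and non-negative")
  tau <- params$d_eff * times / params$radius^2
  small <- times > 0 & tau < .tau_floor
  if (any(small) && !quiet)
    message(sprintf(
      "%d time point(s) below dimensionless time %g returned as 0",
      sum(small), .tau_floor))
  .series_sum(.series_terms_large_l, tau)
}

#' Release profile in dimensionless time
#'
#' Convenience form of the release series as a function of dimensionless
#' time tau = D_eff * t / R^2 and Biot number alone; useful for comparing
#' regimes independent of the physical scales.
#'
#' @param tau Non-negative dimensionless times.
#' @param biot Biot number L; `Inf` (or >= 1e8) selects the
#'   diffusion-controlled limit series.
#' @return Numeric vector of fractions in \[0, 1\].
#' @examples
#' release_profile_tau(0.3, Inf)   # about 0.9685
#' @export
release_profile_tau <- function(tau, biot = Inf) {
  stopifnot(is.numeric(tau))
  if (any(!is.finite(tau)) || any(tau < 0))
    stop("'tau' must be finite and non-negative")
  if (is.infinite(biot) || biot >= 1e8)
    return(.series_sum(.series_terms_large_l, tau))
  if (!is.finite(biot) || biot <= 0) stop("'biot' must be positive")
  .series_sum(function(n) .series_terms_exact(biot, n), tau)
}

#' Time at which a given release fraction is reached
#'
#' Inverts the release series by root finding on log dimensionless time.
#' Used, e.g., to lay out sampling designs spanning a target fraction range.
#'
#' @param params A [model_params()] object.
#' @param fraction Target fraction strictly inside (0, 1).
#' @return Time in seconds.
#' @export
time_at_fraction <- function(params, fraction) {
  stopifnot(inherits(params, "model_params"),
            is.numeric(fraction), length(fraction) == 1L)
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1)
    stop("'fraction' must lie strictly between 0 and 1")
  L <- biot_number(params)
  g <- function(lt) release_profile_tau(exp(lt), L) - fraction
  # release is essentially complete by tau = 10 for any L >= 1e-3
  root <- stats::uniroot(g, lower = log(.tau_floor), upper = log(50),
                         tol = 1e-12)
  exp(root$root) * params$radius^2 / params$d_eff
}

# model_variant dispatch used by the fitter and the simulator
.predict_release <- function(params, times, model_variant = "auto",
                             large_l_threshold = 1e3) {
  switch(model_variant,
    full = fractional_release(params, times, quiet = TRUE),
    simplified = fractional_release_large_l(params, times, quiet = TRUE),
    auto = if (biot_number(params) >= large_l_threshold)
      fractional_release_large_l(params, times, quiet = TRUE)
    else fractional_release(params, times, quiet = TRUE),
    stop("unknown model variant: ", model_variant))
}
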