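#' Eigenvalues of the sphere release model
#'
#' Computes the first `n_terms` positive roots beta_1 < beta_2 < ... of the
#' transcendental equation
#' \deqn{\beta \cot\beta + L - 1 = 0,}
#' which set the exponential decay modes of the release series for a sphere
#' with boundary-layer resistance characterised by the Biot number L.
#'
#' Root n is bracketed in ((n-1)*pi + eps, n*pi - eps) where the residual is
#' guaranteed to change sign (for L <= 1 the first root lies in (eps, pi/2]
#' and that tighter bracket is used). Each bracket is bisected down to a
#' width of 1e-12 and the result polished with a single Newton step; pure
#' Newton is unsafe near the cotangent poles at multiples of pi.
#'
#' @param biot Biot number L, a positive scalar.
#' @param n_terms Number of roots to return, a positive integer.
#' @param tol Residual tolerance. The residual `beta*cot(beta) + L - 1` is
#'   scaled by `max(1, |f'(beta)|)` before comparison: near a root this
#'   scaled residual bounds the error in the root itself, and it remains
#'   attainable at large L where the derivative grows like L^2 and the raw
#'   residual of a machine-precision root does not approach zero.
#' @return An object of class `eigenvalue_set`: a list with `biot`, `roots`
#'   (increasing numeric vector of length `n_terms`) and `n_terms`.
#' @examples
#' solve_eigenvalues(1, 3)$roots / pi      # 0.5, 1.5, 2.5 exactly
#' solve_eigenvalues(1e6, 3)$roots / pi    # close to 1, 2, 3
#' @export
solve_eigenvalues <- function(biot, n_terms, tol = 1e-10) {
  stopifnot(is.numeric(biot), length(biot) == 1L,
            is.numeric(n_terms), length(n_terms) == 1L,
            is.numeric(tol), length(tol) == 1L)
  if (!is.finite(biot) || biot <= 0)
    stop("'biot' must be a positive finite Biot number")
  n_terms <- as.integer(n_terms)
  if (is.na(n_terms) || n_terms < 1L)
    stop("'n_terms' must be a positive integer")
  if (!is.finite(tol) || tol <= 0)
    stop("'tol' must be positive")

  eps <- 1e-9
  n <- seq_len(n_terms)
  lo <- (n - 1) * pi + eps
  hi <- n * pi - eps
  if (biot <= 1) hi[1] <- pi / 2   # equation reduces towards cot(beta) = 0

  f <- function(b) b / tan(b) + biot - 1
  flo <- f(lo)
  fhi <- f(hi)
  # endpoint can be an exact root (L = 1 gives beta_1 = pi/2)
  exact <- abs(fhi) == 0
  bad <- !exact & (sign(flo) == sign(fhi))
  if (any(bad))
    stop(sprintf("failed to bracket eigenvalue %d for Biot number %g",
                 which(bad)[1], biot))

  # vectorised bisection over all brackets simultaneously; the sign at the
  # lower end never changes, so one sign vector classifies every midpoint
  n_iter <- ceiling(log2(pi / 1e-12))
  sgn <- sign(flo)
  for (i in seq_len(n_iter)) {
    mid <- 0.5 * (lo + hi)
    fm <- f(mid)
    sel <- fm * sgn > 0
    lo[sel] <- mid[sel]
    hi[!sel] <- mid[!sel]
  }
  beta <- 0.5 * (lo + hi)
  # one Newton polish: d/db [b*cot(b)] = cot(b) - b/sin(b)^2
  fb <- f(beta)
  dfb <- 1 / tan(beta) - beta / sin(beta)^2
  step <- fb / dfb
  polished <- beta - step
  ok <- is.finite(polished) & polished > (n - 1) * pi & polished < n * pi
  beta <- ifelse(ok & abs(f(polished)) <= abs(fb), polished, beta)

  # scaled residual |f| / max(1, |f'|): near a root this bounds the root
  # error itself, and stays meaningful at large L where f' grows like L^2
  # and the raw residual cannot reach machine precision
  dfb <- 1 / tan(beta) - beta / sin(beta)^2
  res <- abs(f(beta)) / pmax(1, abs(dfb))
  if (any(res >= tol))
    stop(sprintf(
      "eigenvalue %d did not meet the residual tolerance (%.3g >= %.3g)",
      which(res >= tol)[1], max(res), tol))

  structure(list(biot = biot, roots = as.numeric(beta), n_terms = n_terms),
            class = "eigenvalue_set")
}

#' @export
print.eigenvalue_set <- function(x, ...) {
  cat(sprintf("Eigenvalues of beta*cot(beta) + L - 1 = 0, L = %g\n", x$biot))
  k <- min(x$n_terms, 8L)
  cat("  ", paste(sprintf("%.6f", x$roots[seq_len(k)]), collapse = ", "),
      if (x$n_terms > k) sprintf(", ... (%d total)", x$n_terms) else "",
      "\n", sep = "")
  invisible(x)
}
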