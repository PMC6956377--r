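#' A cumulative release curve
#'
#' A time series of cumulative fractional release M_t / M_inf for one
#' replicate. Fractions may be noisy (non-monotone) when they come from
#' measurements; model-generated curves are monotone by construction.
#'
#' @param times Strictly increasing non-negative times, s.
#' @param fractions Cumulative fractional release values. Under
#'   `normalization_mode = "loaded_dose"` all values must be non-negative
#'   (they are fractions of the dose and can stay below 1); under
#'   `"final_observed"` they are normalised to the final released amount.
#' @param replicate_id Replicate label.
#' @param normalization_mode How M_inf was defined: `"final_observed"`
#'   (amount released at the end of the experiment, the definition used by
#'   the series model) or `"loaded_dose"`.
#' @return An object of class `release_curve`.
#' @export
release_curve <- function(times, fractions, replicate_id = "r1",
                          normalization_mode = c("final_observed",
                                                 "loaded_dose")) {
  normalization_mode <- match.arg(normalization_mode)
  stopifnot(is.numeric(times), is.numeric(fractions))
  if (length(times) != length(fractions))
    stop("'times' and 'fractions' must have equal length")
  if (any(!is.finite(times)) || any(times < 0))
    stop("'times' must be finite and non-negative")
  if (any(diff(times) <= 0))
    stop("'times' must be strictly increasing")
  if (any(!is.finite(fractions)))
    stop("'fractions' must be finite")
  if (normalization_mode == "loaded_dose" && any(fractions < 0))
    stop("fractions of the loaded dose must be non-negative")
  structure(list(times = as.numeric(times),
                 fractions = as.numeric(fractions),
                 replicate_id = as.character(replicate_id),
                 normalization_mode = normalization_mode),
            class = "release_curve")
}

#' @export
print.release_curve <- function(x, ...) {
  cat(sprintf("Release curve '%s' (%d points, %s normalisation)\n",
              x$replicate_id, length(x$times), x$normalization_mode))
  cat(sprintf("  time span : %.3g - %.3g s (%.3g - %.3g days)\n",
              min(x$times), max(x$times),
              min(x$times) / 86400, max(x$times) / 86400))
  cat(sprintf("  fractions : %.3g - %.3g\n",
              min(x$fractions), max(x$fractions)))
  invisible(x)
}

#' @export
as.data.frame.release_curve <- function(x, ...) {
  data.frame(replicate = x$replicate_id, time = x$times,
             fraction = x$fractions, stringsAsFactors = FALSE)
}
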