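#' Physical parameters of a single release curve
#'
#' Bundles the three physical constants that govern diffusion-limited release
#' from a sphere suspended in a stirred medium: the effective diffusion
#' coefficient of the drug inside the polymer matrix, the mass-transfer
#' coefficient of the external boundary layer (including any hydrogel shell),
#' and the sphere radius. All values are SI; unit conversion belongs at I/O.
#'
#' @param d_eff Effective diffusion coefficient, m^2/s. Must be positive.
#' @param h Boundary-layer mass-transfer coefficient, m/s. Must be positive.
#' @param radius Sphere radius R, m. Must be positive. The default,
#'   `default_radius()`, is half the 101.4 um volume-median diameter of the
#'   estradiol-loaded microspheres measured by laser diffraction.
#'
#' @return An object of class `model_params`: a named list with elements
#'   `d_eff`, `h`, `radius`.
#' @seealso [biot_number()], [fractional_release()]
#' @examples
#' p <- model_params(d_eff = 5.58e-16, h = 4.01e-10)
#' biot_number(p)
#' @export
model_params <- function(d_eff, h, radius = default_radius()) {
  stopifnot(is.numeric(d_eff), length(d_eff) == 1L,
            is.numeric(h), length(h) == 1L,
            is.numeric(radius), length(radius) == 1L)
  if (!is.finite(d_eff) || d_eff <= 0)
    stop("'d_eff' must be a positive finite diffusion coefficient (m^2/s)")
  if (!is.finite(h) || h <= 0)
    stop("'h' must be a positive finite mass-transfer coefficient (m/s)")
  if (!is.finite(radius) || radius <= 0)
    stop("'radius' must be a positive finite sphere radius (m)")
  structure(list(d_eff = d_eff, h = h, radius = radius),
            class = "model_params")
}

#' Default microsphere radius
#'
#' Half the volume-median diameter (101.4 um) of the drug-loaded microspheres
#' from laser-diffraction sizing, i.e. 50.7 um. The size distribution is wide
#' (10% below 29.7 um, 90% below 198.3 um), so any single-radius choice is a
#' convention; the median is the least surprising one and every function that
#' needs a radius accepts an override.
#'
#' @return Radius in metres (50.7e-6).
#' @export
default_radius <- function() 50.7e-6

#' @export
print.model_params <- function(x, ...) {
  cat("Sphere release model parameters\n")
  cat(sprintf("  D_eff : %.4g m^2/s\n", x$d_eff))
  cat(sprintf("  h     : %.4g m/s\n", x$h))
  cat(sprintf("  R     : %.4g m\n", x$radius))
  cat(sprintf("  Biot L: %.4g\n", biot_number(x)))
  invisible(x)
}

#' Mass-transfer Biot number
#'
#' The dimensionless ratio `L = h * R / D_eff` comparing external
#' boundary-layer mass transfer to internal diffusion. Large L means release
#' is controlled by diffusion inside the sphere; small L means the boundary
#' layer (or a surrounding hydrogel) limits release.
#'
#' @param params A [model_params()] object.
#' @return The Biot number, a positive scalar.
#' @examples
#' biot_number(model_params(d_eff = 5.58e-16, h = 4.01e-10, radius = 50.7e-6))
#' @export
biot_number <- function(params) {
  stopifnot(inherits(params, "model_params"))
  params$h * params$radius / params$d_eff
}
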