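#' Focused-ultrasound transducer description
#'
#' Collects the parameters of the analytic focused-beam pressure model: the
#' source pressure scale \code{Pa}, the lateral beam parameter \code{a_bar}
#' (which sets the lateral focal size), frequency and sound speed, plus the
#' derived wavelength, wavenumber, Rayleigh-like distance
#' \eqn{z_d = k \bar a^2 / 2}, and angular frequency.
#'
#' @param Pa source pressure scale (Pa); sets the focal-center amplitude of
#'   the unattenuated field.
#' @param a_bar lateral beam parameter (m).
#' @param f ultrasound frequency (Hz).
#' @param c0 sound speed in tissue (m/s).
#' @param focus_depth distance from the tissue surface to the focal center
#'   along the beam axis (m).
#' @return Object of class \code{"transducer_spec"}.
#' @examples
#' tr <- transducer_spec(Pa = 2.4e6, a_bar = 0.5e-3, f = 2.5e6,
#'                       c0 = 1540, focus_depth = 10e-3)
#' tr$lambda * 1e6  # wavelength in microns
#' @export
transducer_spec <- function(Pa, a_bar, f, c0, focus_depth = 10e-3) {
  stopifnot(Pa > 0, a_bar > 0, f > 0, c0 > 0, focus_depth >= 0)
  lambda <- c0 / f
  k <- 2 * pi / lambda
  z_d <- k * a_bar^2 / 2
  if (k * z_d <= 1)
    warning("k * z_d <= 1: beam is not in the focused regime")
  structure(list(
    Pa = Pa, a_bar = a_bar, f = f, c0 = c0,
    lambda = lambda, k = k, z_d = z_d,
    omega = 2 * pi * f, focus_depth = focus_depth
  ), class = "transducer_spec")
}

#' @export
print.transducer_spec <- function(x, ...) {
  cat("Focused ultrasound transducer\n")
  cat(sprintf("  Pa = %.3g MPa, a_bar = %.3g mm, f = %.3g MHz\n",
              x$Pa / 1e6, x$a_bar * 1e3, x$f / 1e6))
  cat(sprintf("  lambda = %.0f um, k = %.4g rad/m, z_d = %.3g mm, k*z_d = %.2f\n",
              x$lambda * 1e6, x$k, x$z_d * 1e3, x$k * x$z_d))
  cat(sprintf("  focus depth = %.3g mm\n", x$focus_depth * 1e3))
  invisible(x)
}

# core evaluation of the two-term complex focal pressure at coordinates
# (x, y, z) relative to the focal center; vectorized over equal-length inputs.
# D- = x^2 + y^2 + (z - i z_d)^2 and D+ its conjugate partner; the removable
# singularity sin(k sqrt(D))/sqrt(D) -> k is taken when |D| is tiny.
pressure_kernel <- function(x, y, z, spec) {
  k <- spec$k
  z_d <- spec$z_d
  re <- x^2 + y^2 + z^2 - z_d^2
  im <- 2 * z * z_d
  Dm <- complex(real = re, imaginary = -im)
  Dp <- complex(real = re, imaginary = im)
  sinc_term <- function(D) {
    out <- rep(complex(real = k), length(D))
    ok <- Mod(D) >= 1e-20
    if (any(ok)) {
      s <- sqrt(D[ok])
      out[ok] <- sin(k * s) / s
    }
    out
  }
  spec$Pa * z_d / (2 * sinh(k * z_d)^2) *
    (exp(k * z_d) * sinc_term(Dm) - exp(-k * z_d) * sinc_term(Dp))
}

#' Evaluate the analytic focused-ultrasound pressure amplitude
#'
#' Computes the complex spatial pressure amplitude of a focused beam on a
#' Cartesian grid, optionally applying tissue absorption. The unattenuated
#' field has magnitude exactly \code{Pa} at the focal center. Attenuation can
#' be applied as a depth-varying plane-wave factor \eqn{e^{-\alpha (z + d)}}
#' (default; \eqn{d} = focus depth, so the factor is \eqn{e^{-\alpha d}} at
#' the focal plane) or as a single depth-uniform factor \eqn{e^{-\alpha d}}.
#'
#' @param grid a \code{\link{usf_grid}}.
#' @param spec a \code{\link{transducer_spec}}.
#' @param alpha_np acoustic absorption coefficient (Np/m) at the working
#'   frequency.
#' @param attenuation one of \code{"axial"} (depth-varying, default),
#'   \code{"uniform"} (single factor at the focus depth), or \code{"none"}.
#' @return Object of class \code{"pressure_field"} with the complex amplitude
#'   array \code{P1}, its magnitude \code{p_abs} (Pa), the grid, and the
#'   attenuation metadata.
#' @export
evaluate_pressure <- function(grid, spec, alpha_np = 0,
                              attenuation = c("axial", "uniform", "none")) {
  attenuation <- match.arg(attenuation)
  stopifnot(inherits(grid, "usf_grid"), inherits(spec, "transducer_spec"),
            alpha_np >= 0)
  co <- grid_coords(grid)
  P1 <- pressure_kernel(co[, 1], co[, 2], co[, 3], spec)
  att <- switch(attenuation,
    axial = exp(-alpha_np * (co[, 3] + spec$focus_depth)),
    uniform = exp(-alpha_np * spec$focus_depth),
    none = 1
  )
  P1 <- P1 * att
  if (any(!is.finite(Re(P1)) | !is.finite(Im(P1)))) {
    bad <- which(!is.finite(Re(P1)) | !is.finite(Im(P1)))[1]
    stop(sprintf("non-finite pressure at (x, y, z) = (%g, %g, %g) m",
                 co[bad, 1], co[bad, 2], co[bad, 3]))
  }
  dim(P1) <- grid$dim
  structure(list(
    P1 = P1, p_abs = Mod(P1), grid = grid, spec = spec,
    alpha_np = alpha_np, attenuation = attenuation
  ), class = "pressure_field")
}

#' @export
print.pressure_field <- function(x, ...) {
  cat("Focused ultrasound pressure field\n")
  cat(sprintf("  peak |P1| = %.4g MPa (attenuation: %s, alpha = %.4g Np/m)\n",
              max(x$p_abs) / 1e6, x$attenuation, x$alpha_np))
  print(x$grid)
  invisible(x)
}

#' Acoustic intensity from a pressure field
#'
#' Converts pressure amplitude to intensity, \eqn{I = |P_1|^2 / (2 \rho_0
#' c_0)}, and records the spatial peak and the normalized distribution
#' \eqn{i(r) = I / I_{max}}.
#'
#' @param field a \code{\link{evaluate_pressure}} result.
#' @param rho0 tissue density (kg/m^3).
#' @param c0 sound speed (m/s).
#' @return The field with elements \code{I} (W/m^2), \code{I_max}, and
#'   \code{i_norm} added.
#' @export
intensity_field <- function(field, rho0, c0) {
  stopifnot(inherits(field, "pressure_field"), rho0 > 0, c0 > 0)
  I <- field$p_abs^2 / (2 * rho0 * c0)
  I_max <- max(I)
  if (I_max == 0) stop("degenerate pressure field: I_max == 0")
  field$I <- I
  field$I_max <- I_max
  field$i_norm <- I / I_max
  field$rho0 <- rho0
  field$c0 <- c0
  field
}

#' Volumetric heating source from absorbed ultrasound
#'
#' Builds the volumetric heat generation field
#' \eqn{H(r) = 2 \alpha I(r) = \alpha |P_1|^2 / (\rho_0 c_0)} (W/m^3) with a
#' rectangular exposure schedule active on \eqn{[0, \Delta t)} at 100% duty
#' cycle.
#'
#' @param field a \code{\link{pressure_field}}.
#' @param alpha_np acoustic absorption (Np/m).
#' @param rho0 tissue density (kg/m^3).
#' @param c0 sound speed (m/s).
#' @param exposure ultrasound exposure time \eqn{\Delta t} (s).
#' @return Object of class \code{"heat_source"} with the heating array
#'   \code{H}, the exposure window, and the grid.
#' @export
heating_source <- function(field, alpha_np, rho0, c0, exposure) {
  stopifnot(inherits(field, "pressure_field"), alpha_np >= 0,
            rho0 > 0, c0 > 0, exposure > 0)
  structure(list(
    H = alpha_np * field$p_abs^2 / (rho0 * c0),
    exposure = exposure,
    grid = field$grid
  ), class = "heat_source")
}

#' @export
print.heat_source <- function(x, ...) {
  cat(sprintf("Ultrasound heating source: peak H = %.4g W/m^3, exposure = %g s\n",
              max(x$H), x$exposure))
  invisible(x)
}
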