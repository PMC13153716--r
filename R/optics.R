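SPEED_OF_LIGHT <- 2.99792458e8  # vacuum, m/s

#' Diffuse optical properties of the tissue at one wavelength
#'
#' Derives the quantities used by the semi-infinite photon-diffusion model
#' from the absorption coefficient, reduced scattering coefficient,
#' refractive index and effective surface reflection coefficient:
#' light speed in the medium \eqn{v = c/n}, diffusion coefficient
#' \eqn{D = v / [3(\mu_a + \mu_s')]}, effective attenuation
#' \eqn{\mu_{eff} = \sqrt{3 \mu_a (\mu_a + \mu_s')}}, transport mean free
#' path \eqn{z_{tr} = 1/(\mu_s' + \mu_a)}, and the extrapolation distance
#' \eqn{z_b = [(1 + R_{eff}) / (1 - R_{eff})] \cdot 2 D / v} (length form).
#'
#' @param mu_a absorption coefficient (1/m).
#' @param mu_s_prime reduced scattering coefficient (1/m).
#' @param n refractive index of the tissue.
#' @param R_eff effective reflection coefficient in [0, 1).
#' @param epsilon molar extinction coefficient (1/m/(mol/L)); stored for use
#'   in the emission prefactor.
#' @return Object of class \code{"optical_medium"}.
#' @examples
#' ex <- optical_medium(mu_a = 15, mu_s_prime = 1500)  # 808 nm excitation
#' ex$D      # ~4.95e4 m^2/s
#' ex$z_b    # ~1.24 mm
#' @export
optical_medium <- function(mu_a, mu_s_prime, n = 1.333, R_eff = 0.475,
                           epsilon = NA_real_) {
  stopifnot(mu_a >= 0, mu_s_prime >= 0, n >= 1, R_eff >= 0, R_eff < 1)
  if (mu_a + mu_s_prime == 0) stop("invalid medium: mu_a + mu_s' == 0")
  v <- SPEED_OF_LIGHT / n
  D <- v / (3 * (mu_a + mu_s_prime))
  structure(list(
    n = n, v = v, mu_a = mu_a, mu_s_prime = mu_s_prime,
    D = D,
    mu_eff = sqrt(3 * mu_a * (mu_a + mu_s_prime)),
    R_eff = R_eff,
    z_tr = 1 / (mu_s_prime + mu_a),
    z_b = (1 + R_eff) / (1 - R_eff) * 2 * (D / v),
    epsilon = epsilon
  ), class = "optical_medium")
}

#' @export
print.optical_medium <- function(x, ...) {
  cat("Diffuse optical medium\n")
  cat(sprintf("  mu_a = %g /m, mu_s' = %g /m, n = %g, R_eff = %g\n",
              x$mu_a, x$mu_s_prime, x$n, x$R_eff))
  cat(sprintf("  D = %.4g m^2/s, mu_eff = %.4g /m, z_tr = %.3g mm, z_b = %.3g mm\n",
              x$D, x$mu_eff, x$z_tr * 1e3, x$z_b * 1e3))
  invisible(x)
}

#' Semi-infinite boundary geometry with extrapolated zero boundary
#'
#' Defines the tissue surface (a plane at the transducer focus depth), the
#' extrapolated zero boundary (EZB) planes offset \eqn{z_b} outside the
#' surface, the co-located source-detector position on the surface, the
#' buried excitation point source (depth \eqn{z_{tr}} below the surface),
#' and its image across the excitation EZB. Excitation and emission each
#' carry their own EZB offset by default (their \eqn{z_b} differ slightly);
#' \code{shared_ezb = TRUE} forces both to the excitation plane.
#'
#' Coordinates are in the focal-center frame: origin at the ultrasound
#' focus, +Z the propagation direction. For the \code{"top"} placement the
#' surface is the plane \eqn{z = -d} with outward normal \eqn{-\hat z};
#' \code{"bottom"} puts it at \eqn{z = +d}; \code{"side"} at \eqn{x = -d}.
#'
#' @param focus_depth distance from surface to focal center (m).
#' @param optics_ex,optics_fl \code{\link{optical_medium}} objects for the
#'   excitation and emission wavelengths.
#' @param orientation surface placement relative to the focus:
#'   \code{"top"}, \code{"bottom"}, or \code{"side"}.
#' @param sd_offset in-plane offset (m, length 2) of the co-located
#'   source-detector pair from the focal axis; default on-axis.
#' @param shared_ezb use the excitation EZB for the emission mirror too.
#' @return Object of class \code{"boundary_geometry"} with the surface point
#'   \code{p0}, outward unit normal \code{normal}, source position
#'   \code{r_s}, its image \code{r_s_img}, detector \code{r_D}, and the EZB
#'   offsets \code{z_b_ex}, \code{z_b_fl}.
#' @export
boundary_geometry <- function(focus_depth, optics_ex, optics_fl = optics_ex,
                              orientation = c("top", "bottom", "side"),
                              sd_offset = c(0, 0), shared_ezb = FALSE) {
  orientation <- match.arg(orientation)
  stopifnot(focus_depth > 0, inherits(optics_ex, "optical_medium"),
            inherits(optics_fl, "optical_medium"), length(sd_offset) == 2)
  normal <- switch(orientation,
    top = c(0, 0, -1),
    bottom = c(0, 0, 1),
    side = c(-1, 0, 0)
  )
  p0 <- focus_depth * normal
  # in-plane basis to place the SD pair
  e1 <- switch(orientation, top = c(1, 0, 0), bottom = c(1, 0, 0),
               side = c(0, 0, 1))
  e2 <- c(0, 1, 0)
  r_sd <- p0 + sd_offset[1] * e1 + sd_offset[2] * e2
  z_b_fl <- if (shared_ezb) optics_ex$z_b else optics_fl$z_b
  geom <- structure(list(
    orientation = orientation, focus_depth = focus_depth,
    p0 = p0, normal = normal, e1 = e1, e2 = e2,
    r_D = r_sd,
    r_s = r_sd - optics_ex$z_tr * normal,
    z_b_ex = optics_ex$z_b, z_b_fl = z_b_fl,
    shared_ezb = shared_ezb
  ), class = "boundary_geometry")
  geom$r_s_img <- mirror_across_ezb(geom$r_s, geom, geom$z_b_ex)
  geom
}

#' @export
print.boundary_geometry <- function(x, ...) {
  cat(sprintf("Semi-infinite boundary: %s placement, focus depth %.3g mm\n",
              x$orientation, x$focus_depth * 1e3))
  cat(sprintf("  SD at (%.3g, %.3g, %.3g) mm; source depth z_tr below surface\n",
              x$r_D[1] * 1e3, x$r_D[2] * 1e3, x$r_D[3] * 1e3))
  cat(sprintf("  z_b (ex) = %.3g mm, z_b (fl) = %.3g mm%s\n",
              x$z_b_ex * 1e3, x$z_b_fl * 1e3,
              if (x$shared_ezb) " [shared EZB]" else ""))
  invisible(x)
}

#' Mirror points across an extrapolated zero boundary
#'
#' Reflects points through the EZB plane offset \code{z_b} outside the
#' tissue surface. The map is an involution.
#'
#' @param r point(s): length-3 vector or n x 3 matrix.
#' @param geom a \code{\link{boundary_geometry}}.
#' @param z_b EZB offset (m); defaults to the emission-wavelength offset,
#'   which defines the image volume of the fluorophore distribution.
#' @return Mirrored point(s), same shape as \code{r}.
#' @export
mirror_across_ezb <- function(r, geom, z_b = geom$z_b_fl) {
  stopifnot(inherits(geom, "boundary_geometry"))
  vec <- is.null(dim(r))
  r <- rbind(r)
  s <- (r - matrix(geom$p0, nrow(r), 3, byrow = TRUE)) %*% geom$normal
  out <- r + (2 * z_b - 2 * as.vector(s)) %*% t(geom$normal)
  if (vec) as.vector(out) else out
}

# signed distance along the outward normal (negative strictly inside tissue)
surface_coordinate <- function(r, geom) {
  r <- rbind(r)
  as.vector((r - matrix(geom$p0, nrow(r), 3, byrow = TRUE)) %*% geom$normal)
}

# attenuated spherical kernel exp(-mu |r - r0|)/|r - r0| from a fixed point
# r0 to rows of r; distances below `clamp` are clamped (flagged via attr)
point_kernel <- function(r, r0, mu_eff, clamp = 0) {
  r <- rbind(r)
  d <- sqrt((r[, 1] - r0[1])^2 + (r[, 2] - r0[2])^2 + (r[, 3] - r0[3])^2)
  n_clamped <- 0L
  if (clamp > 0) {
    n_clamped <- sum(d < clamp)
    d <- pmax(d, clamp)
  } else if (any(d == 0)) {
    stop("evaluation point coincides with the kernel source")
  }
  structure(exp(-mu_eff * d) / d, clamped = n_clamped)
}

#' Excitation fluence rate in the semi-infinite medium
#'
#' Two-term image-source solution for the diffuse excitation fluence from
#' the buried point source:
#' \deqn{\phi_{ex}(r) = \frac{v M_0}{4\pi D_{ex}} \left[
#'   \frac{e^{-\mu_{eff} |r_s - r|}}{|r_s - r|} -
#'   \frac{e^{-\mu_{eff} |r_{s'} - r|}}{|r_{s'} - r|} \right].}
#' The fluence vanishes on the excitation EZB plane. The same expression
#' evaluates image-space points.
#'
#' @param geom a \code{\link{boundary_geometry}}.
#' @param medium the excitation \code{\link{optical_medium}}.
#' @param r evaluation point(s): length-3 vector or n x 3 matrix.
#' @param M0 source power (W).
#' @param clamp minimum source distance (m); points closer than this to the
#'   source are clamped for robustness (0 disables).
#' @return List with \code{phi} (W/m^2) and the kernel \code{G} (1/m), each
#'   of length \code{nrow(r)}.
#' @export
excitation_fluence <- function(geom, medium, r, M0 = 1, clamp = 0) {
  stopifnot(inherits(geom, "boundary_geometry"),
            inherits(medium, "optical_medium"))
  G <- point_kernel(r, geom$r_s, medium$mu_eff, clamp) -
    point_kernel(r, geom$r_s_img, medium$mu_eff, clamp)
  list(phi = medium$v * M0 / (4 * pi * medium$D) * as.vector(G),
       G = as.vector(G))
}

#' Emission propagation kernel
#'
#' Attenuated spherical kernel for fluorescence photons from an interior
#' point to the detector,
#' \eqn{G_{fl}(r, r_D) = e^{-\mu_{eff} |r - r_D|} / |r - r_D|}. The image
#' contribution of an emitter is obtained by evaluating the same kernel
#' from the mirrored emitter position.
#'
#' @param r emitter point(s): length-3 vector or n x 3 matrix.
#' @param r_D detector position (length-3).
#' @param medium the emission \code{\link{optical_medium}}.
#' @param clamp minimum distance (m) before clamping (0 disables).
#' @return Kernel values (1/m), length \code{nrow(r)}.
#' @export
emission_green <- function(r, r_D, medium, clamp = 0) {
  stopifnot(inherits(medium, "optical_medium"))
  as.vector(point_kernel(r, r_D, medium$mu_eff, clamp))
}
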