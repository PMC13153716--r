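#' Fluorophore concentration map on the thermal grid
#'
#' Builds the nanoagent molar concentration field \eqn{C(r)} for the
#' standard simulation scenarios: a single voxel at the focal center, two
#' voxels separated along one axis, a uniform fill, or a custom array.
#'
#' @param grid a \code{\link{usf_grid}} (the thermal grid).
#' @param scenario one of \code{"single_voxel"}, \code{"two_voxel"},
#'   \code{"uniform"}, \code{"custom"}.
#' @param C0 concentration in filled voxels (mol/L).
#' @param separation for \code{"two_voxel"}: center-to-center separation (m);
#'   rounded to the nearest whole voxel along \code{axis}.
#' @param axis separation axis for \code{"two_voxel"}.
#' @param C custom concentration array (required for \code{"custom"}).
#' @return Object of class \code{"nanoagent_map"}.
#' @export
nanoagent_map <- function(grid, scenario = c("single_voxel", "two_voxel",
                                             "uniform", "custom"),
                          C0 = 4.4e-11, separation = 0.3e-3,
                          axis = c("x", "y", "z"), C = NULL) {
  scenario <- match.arg(scenario)
  axis <- match.arg(axis)
  stopifnot(inherits(grid, "usf_grid"), C0 >= 0)
  ctr <- grid_center(grid)
  arr <- array(0, grid$dim)
  sep_actual <- NA_real_
  if (scenario == "single_voxel") {
    arr[ctr[1], ctr[2], ctr[3]] <- C0
  } else if (scenario == "two_voxel") {
    d_ax <- switch(axis, x = grid$dx, y = grid$dy, z = grid$dz)
    off <- round(separation / d_ax)
    if (off == 0) {
      arr[ctr[1], ctr[2], ctr[3]] <- C0  # degenerate: both points coincide
    } else {
      idx2 <- ctr + switch(axis, x = c(off, 0, 0), y = c(0, off, 0),
                           z = c(0, 0, off))
      if (any(idx2 < 1) || any(idx2 > grid$dim))
        stop("second voxel placed outside the grid")
      arr[ctr[1], ctr[2], ctr[3]] <- C0
      arr[idx2[1], idx2[2], idx2[3]] <- C0
    }
    sep_actual <- off * d_ax
  } else if (scenario == "uniform") {
    arr[] <- C0
  } else {
    if (is.null(C) || !identical(dim(C), as.integer(grid$dim)) &&
        !identical(dim(C), grid$dim))
      stop("custom scenario requires a concentration array matching the grid")
    if (any(C < 0)) stop("concentrations must be non-negative")
    arr <- C
  }
  structure(list(C = arr, grid = grid, scenario = scenario,
                 separation = sep_actual, axis = axis),
            class = "nanoagent_map")
}

#' @export
print.nanoagent_map <- function(x, ...) {
  cat(sprintf("Nanoagent concentration map: %s, %d filled voxel(s), max C = %g mol/L\n",
              x$scenario, sum(x$C > 0), max(x$C)))
  if (x$scenario == "two_voxel")
    cat(sprintf("  separation %.3g mm along %s\n", x$separation * 1e3, x$axis))
  invisible(x)
}

#' Source-detector configuration
#'
#' Excitation power and emission molar extinction entering the USF signal
#' prefactor, \eqn{K = v^2 M_0 \varepsilon_{fl} / ((4\pi)^2 D_{ex} D_{fl})}.
#' Source and detector positions themselves live in the
#' \code{\link{boundary_geometry}} (co-located by default).
#'
#' @param M0 excitation power (W).
#' @param epsilon_fl emission molar extinction coefficient (1/m/(mol/L)).
#' @return Object of class \code{"sd_config"}.
#' @export
sd_config <- function(M0 = 0.003, epsilon_fl = 6.54e5) {
  stopifnot(M0 > 0, epsilon_fl > 0)
  structure(list(M0 = M0, epsilon_fl = epsilon_fl), class = "sd_config")
}

# signal prefactor K
usf_prefactor <- function(optics_ex, optics_fl, sd) {
  optics_ex$v * optics_fl$v * sd$M0 * sd$epsilon_fl /
    ((4 * pi)^2 * optics_ex$D * optics_fl$D)
}

# static per-voxel kernel terms for rows of coordinates r. The direct term
# is G_ex(r) G_fl(r, r_D); the image term mirrors the emitter across the
# emission EZB with unchanged strength, G_ex(r) G_fl(r_i, r_D), and is
# subtracted by the caller so the emission fluence vanishes on the EZB
# (equivalently, G_fl(r, r_D) - G_fl(r_i, r_D) is the semi-infinite
# emission Green's function).
usf_kernel_diff <- function(r, geom, optics_ex, optics_fl, r_D = geom$r_D,
                            clamp = 0) {
  ri <- mirror_across_ezb(r, geom, geom$z_b_fl)
  gex_r <- excitation_fluence(geom, optics_ex, r, M0 = 1, clamp = clamp)$G
  gfl_r <- emission_green(r, r_D, optics_fl, clamp = clamp)
  gfl_i <- emission_green(ri, r_D, optics_fl, clamp = clamp)
  list(direct = gex_r * gfl_r, image = gex_r * gfl_i)
}

#' Time-resolved USF signal
#'
#' Assembles the dynamic USF signal for a detector on the surface by
#' midpoint-rule summation over the fluorophore-filled voxels:
#' \deqn{\phi_{USF}(t) = K \left[ \sum_F G_{ex}(r) C(r) Q(T(r,t))
#'   G_{fl}(r, r_D) \, d\Omega - \sum_{F'} (\mathrm{image\ term}) \right]}
#' with the background (pre-ultrasound) fluorescence subtracted, so
#' \eqn{\phi_{USF}(0) = 0}. The image volume \eqn{F'} mirrors the
#' concentration and temperature fields across the emission EZB.
#'
#' @param thermal a \code{\link{solve_bioheat}} result whose snapshots set
#'   the time axis.
#' @param map a \code{\link{nanoagent_map}} on the same grid.
#' @param agent a \code{\link{nanoagent_spec}}.
#' @param geom a \code{\link{boundary_geometry}}.
#' @param optics_ex,optics_fl \code{\link{optical_medium}} objects.
#' @param sd a \code{\link{sd_config}}.
#' @return Object of class \code{"usf_series"} with \code{t} (s), the
#'   background-subtracted signal \code{phi} (W/m^2), the raw background
#'   \code{phi_baseline}, the focal temperature-rise trace \code{dT_focal},
#'   and the inputs needed for velocity evaluation.
#' @export
usf_signal <- function(thermal, map, agent, geom, optics_ex, optics_fl,
                       sd = sd_config()) {
  stopifnot(inherits(thermal, "thermal_field"), inherits(map, "nanoagent_map"),
            inherits(agent, "nanoagent_spec"),
            inherits(geom, "boundary_geometry"))
  if (!identical(thermal$grid$dim, map$grid$dim))
    stop("thermal grid and concentration grid do not match")
  grid <- thermal$grid
  idx <- which(map$C > 0)
  if (length(idx) == 0L) stop("concentration map is empty")
  co <- grid_coords(grid)[idx, , drop = FALSE]
  cv <- map$C[idx]
  ker <- usf_kernel_diff(co, geom, optics_ex, optics_fl)
  K <- usf_prefactor(optics_ex, optics_fl, sd)
  dV <- grid$dV
  Q_bg <- quantum_yield(agent$T_BG, agent)
  baseline <- K * dV * sum(cv * Q_bg * (ker$direct - ker$image))
  ctr <- grid_center(grid)
  nt <- length(thermal$times)
  phi <- dT_focal <- numeric(nt)
  for (i in seq_len(nt)) {
    dTi <- thermal$dT[[i]]
    Q <- quantum_yield(agent$T_BG + dTi[idx], agent)
    phi[i] <- K * dV * sum(cv * Q * (ker$direct - ker$image)) - baseline
    dT_focal[i] <- dTi[ctr[1], ctr[2], ctr[3]]
  }
  structure(list(
    t = thermal$times, phi = phi, phi_baseline = baseline,
    dT_focal = dT_focal,
    thermal = thermal, map = map, agent = agent, geom = geom,
    optics_ex = optics_ex, optics_fl = optics_fl, sd = sd,
    kernel = ker, support = idx
  ), class = "usf_series")
}

#' @export
print.usf_series <- function(x, ...) {
  cat(sprintf("USF time series: %d snapshots on [%g, %g] s (%s map)\n",
              length(x$t), min(x$t), max(x$t), x$map$scenario))
  cat(sprintf("  peak signal %.4g W/m^2 at t = %g s; baseline %.4g W/m^2\n",
              max(x$phi), x$t[which.max(x$phi)], x$phi_baseline))
  invisible(x)
}

#' @export
plot.usf_series <- function(x, normalize = TRUE, ...) {
  v <- usf_velocity(x)
  s <- if (normalize && max(abs(x$phi)) > 0) x$phi / max(abs(x$phi)) else x$phi
  vv <- if (normalize && max(abs(v$velocity)) > 0)
    v$velocity / max(abs(v$velocity)) else v$velocity
  graphics::plot(x$t, s, type = "l", col = "blue",
                 xlab = "time (s)", ylab = "normalized signal / velocity", ...)
  graphics::lines(x$t, vv, col = "darkgreen")
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topright", legend = c("USF signal", "velocity"),
                   col = c("blue", "darkgreen"), lty = 1, bty = "n")
  invisible(x)
}

#' Velocity (and acceleration) of the USF signal
#'
#' First time derivative of the USF signal. \code{mode = "numeric"}
#' (default) differentiates the sampled signal by central differences;
#' \code{mode = "analytic"} evaluates the derivative integral directly,
#' summing \eqn{G_{ex} C \, (dQ/dT) (dT/dt) \, G_{fl}} (minus the image
#' term) with the yield derivative and the solver's temperature rate.
#'
#' @param series a \code{\link{usf_signal}} result.
#' @param mode \code{"numeric"} or \code{"analytic"}.
#' @return List with \code{t}, \code{velocity}, and \code{acceleration}
#'   (second difference; numeric mode only).
#' @export
usf_velocity <- function(series, mode = c("numeric", "analytic")) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "usf_series"))
  tt <- series$t
  n <- length(tt)
  if (mode == "numeric") {
    if (n < 3) stop("numeric differentiation needs at least 3 snapshots")
    v <- finite_diff(tt, series$phi)
    a <- finite_diff(tt, v)
    return(list(t = tt, velocity = v, acceleration = a, mode = mode))
  }
  thermal <- series$thermal
  if (is.null(thermal$dTdt))
    stop("analytic velocity needs a thermal field with >= 2 snapshots")
  idx <- series$support
  cv <- series$map$C[idx]
  ker <- series$kernel
  K <- usf_prefactor(series$optics_ex, series$optics_fl, series$sd)
  dV <- series$map$grid$dV
  v <- numeric(n)
  for (i in seq_len(n)) {
    T_i <- series$agent$T_BG + thermal$dT[[i]][idx]
    v[i] <- K * dV * sum(cv * yield_derivative(T_i, series$agent) *
                           thermal$dTdt[[i]][idx] *
                           (ker$direct - ker$image))
  }
  list(t = tt, velocity = v, acceleration = NULL, mode = mode)
}

# central differences on a possibly non-uniform time axis
finite_diff <- function(t, y) {
  n <- length(t)
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  d[1] <- (y[2] - y[1]) / (t[2] - t[1])
  d[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  d
}

#' Surface distribution (PSF map) of the USF signal
#'
#' Evaluates the background-subtracted USF signal over a raster of detector
#' positions on the tissue surface at one snapshot time, giving the
#' point-spread map a camera would record.
#'
#' @inheritParams usf_signal
#' @param t snapshot time; must be one of the thermal snapshot times.
#' @param raster_u,raster_v in-plane detector offsets (m) along the surface
#'   basis vectors.
#' @param normalize divide by the map maximum.
#' @return Object of class \code{"usf_surface_map"}: matrix \code{map}
#'   (length(u) x length(v)), the raster axes, and the snapshot time.
#' @export
surface_map <- function(thermal, map, agent, geom, optics_ex, optics_fl,
                        sd = sd_config(), t,
                        raster_u = seq(-10e-3, 10e-3, by = 1e-3),
                        raster_v = raster_u, normalize = FALSE) {
  it <- match(t, thermal$times)
  if (is.na(it)) stop("t must be one of the thermal snapshot times")
  grid <- thermal$grid
  idx <- which(map$C > 0)
  co <- grid_coords(grid)[idx, , drop = FALSE]
  cv <- map$C[idx]
  K <- usf_prefactor(optics_ex, optics_fl, sd)
  Q_bg <- quantum_yield(agent$T_BG, agent)
  Q <- quantum_yield(agent$T_BG + thermal$dT[[it]][idx], agent)
  out <- matrix(0, length(raster_u), length(raster_v))
  for (iu in seq_along(raster_u)) {
    for (iv in seq_along(raster_v)) {
      r_D <- geom$p0 + raster_u[iu] * geom$e1 + raster_v[iv] * geom$e2
      ker <- usf_kernel_diff(co, geom, optics_ex, optics_fl, r_D = r_D)
      kd <- ker$direct - ker$image
      out[iu, iv] <- K * grid$dV * sum(cv * (Q - Q_bg) * kd)
    }
  }
  if (normalize && max(abs(out)) > 0) out <- out / max(abs(out))
  structure(list(map = out, u = raster_u, v = raster_v, t = t,
                 normalized = normalize),
            class = "usf_surface_map")
}

#' @export
print.usf_surface_map <- function(x, ...) {
  cat(sprintf("USF surface map at t = %g s: %d x %d raster, peak %.4g%s\n",
              x$t, length(x$u), length(x$v), max(x$map),
              if (x$normalized) " (normalized)" else " W/m^2"))
  invisible(x)
}

#' @export
plot.usf_surface_map <- function(x, ...) {
  graphics::image(x$u * 1e3, x$v * 1e3, x$map,
                  xlab = "u (mm)", ylab = "v (mm)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

# sub-sample localization of the maximum by parabolic interpolation
peak_time <- function(t, v) {
  i <- which.max(v)
  if (i == 1L || i == length(v))
    stop("velocity pulse not resolved: increase temporal sampling")
  # uniform-spacing parabola through (i-1, i, i+1)
  denom <- v[i - 1] - 2 * v[i] + v[i + 1]
  if (denom == 0) return(t[i])
  t[i] + 0.5 * (v[i - 1] - v[i + 1]) / denom * (t[i + 1] - t[i])
}

# FWHM of the positive lobe of a velocity trace
positive_pulse_fwhm <- function(t, v) {
  vp <- pmax(v, 0)
  if (max(vp) <= 0) stop("no positive velocity pulse")
  profile_fwhm(t, vp)
}

#' Two-point temporal-separability experiment
#'
#' Places two unit fluorophore voxels in the focal volume (one at the focal
#' center, the second offset by \code{separation} along \code{axis}),
#' simulates their individual and combined USF signals, and measures the
#' temporal observables that carry sub-focal structure: the delay
#' \code{dt_X12} between the two positive velocity peaks (sub-sample
#' parabolic localization) and the width \code{dt_v} of the first point's
#' positive velocity pulse (FWHM).
#'
#' @inheritParams usf_signal
#' @param separation center-to-center separation (m).
#' @param axis separation axis.
#' @param C0 voxel concentration (mol/L).
#' @return List with the three \code{usf_series} (\code{series_X1},
#'   \code{series_X2}, \code{series_combined}), their numeric velocities,
#'   \code{dt_X12} (s), \code{dt_v} (s), and the realized separation (m).
#' @export
two_point_experiment <- function(separation, thermal, agent, geom,
                                 optics_ex, optics_fl, sd = sd_config(),
                                 axis = c("x", "y", "z"), C0 = 4.4e-11) {
  axis <- match.arg(axis)
  grid <- thermal$grid
  ctr <- grid_center(grid)
  d_ax <- switch(axis, x = grid$dx, y = grid$dy, z = grid$dz)
  off <- round(separation / d_ax)
  map1 <- nanoagent_map(grid, "single_voxel", C0 = C0)
  C2 <- array(0, grid$dim)
  idx2 <- ctr + switch(axis, x = c(off, 0, 0), y = c(0, off, 0),
                       z = c(0, 0, off))
  if (any(idx2 < 1) || any(idx2 > grid$dim))
    stop("second point falls outside the thermal grid")
  C2[idx2[1], idx2[2], idx2[3]] <- C0
  map2 <- nanoagent_map(grid, "custom", C = C2)
  map12 <- nanoagent_map(grid, "two_voxel", C0 = C0,
                         separation = separation, axis = axis)
  s1 <- usf_signal(thermal, map1, agent, geom, optics_ex, optics_fl, sd)
  s2 <- usf_signal(thermal, map2, agent, geom, optics_ex, optics_fl, sd)
  s12 <- usf_signal(thermal, map12, agent, geom, optics_ex, optics_fl, sd)
  v1 <- usf_velocity(s1)
  v2 <- usf_velocity(s2)
  tp1 <- peak_time(v1$t, v1$velocity)
  tp2 <- if (off == 0) tp1 else peak_time(v2$t, v2$velocity)
  list(
    series_X1 = s1, series_X2 = s2, series_combined = s12,
    velocity_X1 = v1, velocity_X2 = v2,
    dt_X12 = tp2 - tp1,
    dt_v = positive_pulse_fwhm(v1$t, v1$velocity),
    separation = off * d_ax
  )
}
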