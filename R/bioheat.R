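#' Tissue thermal and perfusion properties
#'
#' Parameters of the Pennes bioheat model: tissue and blood density, specific
#' heats, thermal conductivity, blood perfusion rate, and background
#' temperature, together with the derived thermal diffusivity
#' \eqn{\alpha_{th} = k_t / (\rho_0 C_t)} and perfusion time constant
#' \eqn{\tau = \rho_0 C_t / (\omega_b \rho_b C_b)}.
#'
#' @param rho0,rho_b tissue / blood density (kg/m^3).
#' @param Ct,Cb tissue / blood specific heat (J/kg/K).
#' @param kt tissue thermal conductivity (W/m/K).
#' @param omega_b blood perfusion rate (1/s).
#' @param T_BG background temperature (degrees C).
#' @return Object of class \code{"tissue_thermal"}.
#' @examples
#' tt <- tissue_thermal()   # soft-tissue defaults
#' tt$alpha_th              # ~1.34e-7 m^2/s
#' tt$tau                   # ~59 s
#' @export
tissue_thermal <- function(rho0 = 1064, rho_b = 1060, Ct = 4200, Cb = 3780,
                           kt = 0.6, omega_b = 0.0189, T_BG = 37) {
  vals <- c(rho0, rho_b, Ct, Cb, kt, omega_b)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all thermal parameters must be positive and finite")
  structure(list(
    rho0 = rho0, rho_b = rho_b, Ct = Ct, Cb = Cb, kt = kt,
    omega_b = omega_b, T_BG = T_BG,
    alpha_th = kt / (rho0 * Ct),
    tau = rho0 * Ct / (omega_b * rho_b * Cb)
  ), class = "tissue_thermal")
}

#' @export
print.tissue_thermal <- function(x, ...) {
  cat("Tissue thermal properties (Pennes model)\n")
  cat(sprintf("  rho0 = %g, Ct = %g, kt = %g, omega_b = %g, T_BG = %g C\n",
              x$rho0, x$Ct, x$kt, x$omega_b, x$T_BG))
  cat(sprintf("  alpha_th = %.4g m^2/s, perfusion tau = %.3g s\n",
              x$alpha_th, x$tau))
  invisible(x)
}

#' Stable explicit time step for the bioheat solver
#'
#' Stability bound of the forward-time central-space scheme,
#' \eqn{dt = s / (2 \alpha_{th} (1/dx^2 + 1/dy^2 + 1/dz^2))}, additionally
#' capped at \eqn{s \tau / 10} so the perfusion sink is well resolved.
#'
#' @param grid a \code{\link{usf_grid}}.
#' @param tissue a \code{\link{tissue_thermal}}.
#' @param safety factor in (0, 1].
#' @return Time step (s).
#' @export
stable_timestep <- function(grid, tissue, safety = 0.9) {
  stopifnot(safety > 0, safety <= 1)
  dt_diff <- safety / (2 * tissue$alpha_th *
                         (1 / grid$dx^2 + 1 / grid$dy^2 + 1 / grid$dz^2))
  min(dt_diff, safety * tissue$tau / 10)
}

# 7-point Laplacian with zero-gradient (mirror) faces
laplacian_mirror <- function(u, nx, ny, nz, dx2, dy2, dz2) {
  (u[c(2:nx, nx), , ] + u[c(1, 1:(nx - 1)), , ] - 2 * u) / dx2 +
    (u[, c(2:ny, ny), ] + u[, c(1, 1:(ny - 1)), ] - 2 * u) / dy2 +
    (u[, , c(2:nz, nz)] + u[, , c(1, 1:(nz - 1))] - 2 * u) / dz2
}

#' Solve the Pennes bioheat equation for the ultrasound-induced rise
#'
#' Explicit forward-time central-space integration of
#' \deqn{\rho_0 C_t \partial_t \Delta T = k_t \nabla^2 \Delta T -
#'       \omega_b \rho_b C_b \Delta T + H(r) s(t)}
#' with zero initial condition and zero-gradient boundaries, where
#' \eqn{s(t)} is the rectangular exposure window of the heat source. The
#' internal step is shortened locally so every requested snapshot time is
#' hit exactly (no temporal interpolation); the exposure edge is likewise a
#' step boundary.
#'
#' @param source a \code{\link{heating_source}} on the same grid.
#' @param tissue a \code{\link{tissue_thermal}}.
#' @param grid a \code{\link{usf_grid}} matching the source.
#' @param snapshot_times sorted non-negative times (s) at which the full
#'   \eqn{\Delta T} volume is stored.
#' @param safety explicit stability safety factor.
#' @param probe_index optional integer matrix (rows of \code{(i, j, k)} array
#'   indices); if given, \eqn{\Delta T} at those voxels is recorded at every
#'   internal step and returned as \code{probes}.
#' @return Object of class \code{"thermal_field"}: \code{times}, list
#'   \code{dT} of snapshot arrays (K), \code{dTdt} (K/s, central differences
#'   across snapshots), the grid, tissue, exposure, and optional probe
#'   series.
#' @export
solve_bioheat <- function(source, tissue, grid, snapshot_times,
                          safety = 0.9, probe_index = NULL) {
  stopifnot(inherits(source, "heat_source"), inherits(tissue, "tissue_thermal"),
            inherits(grid, "usf_grid"))
  if (!identical(dim(source$H), as.integer(grid$dim)) &&
      !identical(dim(source$H), grid$dim))
    stop("heat source grid does not match the thermal grid")
  snapshot_times <- as.numeric(snapshot_times)
  if (is.unsorted(snapshot_times, strictly = TRUE) || any(snapshot_times < 0))
    stop("snapshot times must be sorted, distinct, and >= 0")
  dt_max <- stable_timestep(grid, tissue, safety)

  nx <- grid$dim[1]; ny <- grid$dim[2]; nz <- grid$dim[3]
  dx2 <- grid$dx^2; dy2 <- grid$dy^2; dz2 <- grid$dz^2
  a <- tissue$alpha_th
  perf <- tissue$omega_b * tissue$rho_b * tissue$Cb / (tissue$rho0 * tissue$Ct)
  Hs <- source$H / (tissue$rho0 * tissue$Ct)

  # segment edges: snapshots plus the exposure boundary
  edges <- sort(unique(c(snapshot_times, source$exposure)))
  edges <- edges[edges > 0 & edges <= max(snapshot_times)]
  u <- array(0, grid$dim)
  t_cur <- 0
  snaps <- vector("list", length(snapshot_times))
  names(snaps) <- as.character(snapshot_times)
  if (0 %in% snapshot_times) snaps[[as.character(0)]] <- u
  probes <- NULL
  if (!is.null(probe_index)) {
    probe_index <- rbind(probe_index)
    plin <- probe_index[, 1] + nx * (probe_index[, 2] - 1L) +
      nx * ny * (probe_index[, 3] - 1L)
    probes <- list(t = 0, dT = matrix(0, nrow = 1, ncol = length(plin)))
  }
  for (te in edges) {
    n_step <- max(1L, ceiling((te - t_cur) / dt_max))
    dt <- (te - t_cur) / n_step
    heating <- t_cur < source$exposure   # window active on [0, exposure)
    for (s in seq_len(n_step)) {
      du <- a * laplacian_mirror(u, nx, ny, nz, dx2, dy2, dz2) - perf * u
      if (heating) du <- du + Hs
      u <- u + dt * du
      t_cur <- t_cur + dt
      if (!is.null(probes)) {
        probes$t <- c(probes$t, t_cur)
        probes$dT <- rbind(probes$dT, u[plin])
      }
    }
    t_cur <- te  # remove accumulated round-off at segment edges
    if (te %in% snapshot_times) snaps[[as.character(te)]] <- u
  }
  dT <- snaps[as.character(snapshot_times)]
  field <- structure(list(
    times = snapshot_times, dT = dT, grid = grid, tissue = tissue,
    exposure = source$exposure, probes = probes
  ), class = "thermal_field")
  field$dTdt <- thermal_time_derivative(field)
  field
}

# central differences of snapshot volumes (one-sided at the ends);
# NULL when fewer than two snapshots were stored
thermal_time_derivative <- function(field) {
  tt <- field$times
  n <- length(tt)
  if (n < 2) return(NULL)
  d <- vector("list", n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - 1L)
    hi <- min(n, i + 1L)
    d[[i]] <- (field$dT[[hi]] - field$dT[[lo]]) / (tt[hi] - tt[lo])
  }
  names(d) <- names(field$dT)
  d
}

#' @export
print.thermal_field <- function(x, ...) {
  pk <- vapply(x$dT, max, numeric(1))
  cat("Bioheat temperature-rise field\n")
  cat(sprintf("  exposure %g s; %d snapshots: %s s\n", x$exposure,
              length(x$times), paste(format(x$times), collapse = ", ")))
  cat(sprintf("  peak dT per snapshot (K): %s\n",
              paste(sprintf("%.3f", pk), collapse = ", ")))
  invisible(x)
}

#' @export
summary.thermal_field <- function(object, ...) {
  ctr <- grid_center(object$grid)
  focal <- vapply(object$dT, function(u) u[ctr[1], ctr[2], ctr[3]], numeric(1))
  out <- data.frame(
    time_s = object$times,
    peak_dT_K = vapply(object$dT, max, numeric(1)),
    focal_dT_K = focal
  )
  lat <- ax <- rep(NA_real_, length(object$times))
  for (i in seq_along(object$times)) {
    pr <- center_profile(object$dT[[i]], object$grid, "x")
    lat[i] <- tryCatch(profile_fwhm(pr$coord, pr$value), error = function(e) NA)
    pr <- center_profile(object$dT[[i]], object$grid, "z")
    ax[i] <- tryCatch(profile_fwhm(pr$coord, pr$value), error = function(e) NA)
  }
  out$lateral_fwhm_mm <- lat * 1e3
  out$axial_fwhm_mm <- ax * 1e3
  out
}

#' Thermal-confinement temperature rise
#'
#' Closed-form temperature rise when thermal diffusion and perfusion are
#' neglected during the exposure: \eqn{\Delta T(r, t) = H(r) t / (\rho_0
#' C_t)}. Its spatial shape equals the normalized intensity distribution.
#'
#' @param source a \code{\link{heating_source}}.
#' @param tissue a \code{\link{tissue_thermal}}.
#' @param t time within the exposure (s).
#' @return Array of \eqn{\Delta T} (K) on the source grid.
#' @export
confinement_temperature <- function(source, tissue, t) {
  stopifnot(inherits(source, "heat_source"), t >= 0)
  if (t > source$exposure)
    stop("confinement form only applies within the exposure window")
  source$H * t / (tissue$rho0 * tissue$Ct)
}

#' Perfusion time constant, exposure attenuation, and diffusion length
#'
#' Summary metrics of heat loss during an exposure: the perfusion time
#' constant \eqn{\tau}, the perfusion-related attenuation fraction
#' \eqn{1 - e^{-\Delta t / \tau}}, and the transient conduction length
#' \eqn{L_d = \sqrt{4 \alpha_{th} \Delta t}}.
#'
#' @param tissue a \code{\link{tissue_thermal}}.
#' @param exposure_dt exposure time (s).
#' @return List with \code{tau} (s), \code{attenuation_fraction}, and
#'   \code{L_d} (m).
#' @examples
#' perfusion_metrics(tissue_thermal(), 0.4)
#' @export
perfusion_metrics <- function(tissue, exposure_dt) {
  stopifnot(inherits(tissue, "tissue_thermal"), exposure_dt > 0)
  list(
    tau = tissue$tau,
    attenuation_fraction = 1 - exp(-exposure_dt / tissue$tau),
    L_d = sqrt(4 * tissue$alpha_th * exposure_dt)
  )
}
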