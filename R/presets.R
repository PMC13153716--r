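# pipeline helpers shared by the presets ------------------------------------

# pressure + intensity on a grid described by a config block
preset_pressure <- function(cfg, obj, grid_block = "thermal") {
  gb <- cfg$grids[[grid_block]]
  grid <- usf_grid(gb$dx, gb$dy, gb$dz, gb$Lx, gb$Ly, gb$Lz)
  field <- evaluate_pressure(grid, obj$spec, obj$alpha_np,
                             attenuation = cfg$attenuation)
  intensity_field(field, cfg$tissue$rho0, cfg$transducer$c0)
}

# bioheat solve driven by a config; snapshot_times on the given grid block
preset_thermal <- function(cfg, obj, snapshot_times, grid_block = "thermal") {
  field <- preset_pressure(cfg, obj, grid_block)
  src <- heating_source(field, obj$alpha_np, cfg$tissue$rho0,
                        cfg$transducer$c0, cfg$timing$exposure)
  solve_bioheat(src, obj$tissue, field$grid, snapshot_times)
}

# dynamics-cadence snapshot times from the timing block
preset_times <- function(cfg) {
  round(seq(0, cfg$timing$total, by = cfg$timing$cadence), 10)
}

#' Run a named figure-reproduction preset
#'
#' Executes one of the canned simulation pipelines end to end and returns
#' its outputs as a named list; optionally writes CSV/JSON (and TIFF, when
#' the \pkg{tiff} package is installed) artifacts to \code{out_dir}.
#'
#' \describe{
#'   \item{\code{fig2}}{Pressure-field FWHMs on the fine acoustic sampling,
#'     bioheat snapshots at 0.149/0.397/0.521/0.708 s on the 50 x 50 x 175
#'     um thermal grid, their thermal FWHMs, and the focal temperature
#'     trace.}
#'   \item{\code{fig3}}{Quantum-yield curve, its derivative, and the
#'     switching parameters recovered from the sampled curve.}
#'   \item{\code{fig4_single}, \code{fig4_uniform}}{Dynamic USF signal and
#'     velocity for a single focal voxel / a uniform fill, on the dynamics
#'     grid at the configured cadence, plus surface PSF maps at the four
#'     reporting times.}
#'   \item{\code{fig5}}{Two-point experiment at the configured separation:
#'     per-point and combined series, velocity-peak delay and pulse width.}
#'   \item{\code{fig6}, \code{fig7}}{Signal (\code{fig6}) or velocity
#'     (\code{fig7}) sensitivity matrices for top/bottom/side SD
#'     placements, frames 0 to 0.35 s step 0.05 s, globally normalized.}
#' }
#'
#' @param name preset name.
#' @param cfg a \code{\link{usf_config}}; defaults reproduce the standard
#'   parameter set.
#' @param out_dir optional output directory.
#' @return Named list of results (contents vary by preset); the run
#'   metadata is attached as \code{meta}.
#' @export
run_preset <- function(name = c("fig2", "fig3", "fig4_single", "fig4_uniform",
                                "fig5", "fig6", "fig7"),
                       cfg = usf_config(), out_dir = NULL) {
  name <- match.arg(name)
  cfg <- validate_config(cfg)
  obj <- config_objects(cfg)
  t0 <- proc.time()[3]
  out <- switch(name,
    fig2 = preset_fig2(cfg, obj),
    fig3 = preset_fig3(cfg, obj),
    fig4_single = preset_fig4(cfg, obj, "single_voxel"),
    fig4_uniform = preset_fig4(cfg, obj, "uniform"),
    fig5 = preset_fig5(cfg, obj),
    fig6 = preset_fig67(cfg, obj, "signal"),
    fig7 = preset_fig67(cfg, obj, "velocity")
  )
  out$meta <- list(preset = name, runtime_s = unname(proc.time()[3] - t0),
                   config = unclass(cfg))
  if (!is.null(out_dir)) write_preset_outputs(out, name, out_dir)
  out
}

preset_fig2 <- function(cfg, obj) {
  # fine-sampling 1-D profiles for the acoustic FWHMs
  ga <- cfg$grids$acoustic
  prof_x <- pressure_axis_profile(obj$spec, obj$alpha_np, cfg$attenuation,
                                  "x", ga$dx, ga$Lx)
  prof_z <- pressure_axis_profile(obj$spec, obj$alpha_np, cfg$attenuation,
                                  "z", ga$dz, ga$Lz)
  snaps <- c(0.149, 0.397, 0.521, 0.708)
  thermal <- preset_thermal(cfg, obj, snaps)
  list(
    pressure_peak_MPa = max(prof_x$value) / 1e6,
    fwhm_lateral_mm = profile_fwhm(prof_x$coord, prof_x$value) * 1e3,
    fwhm_axial_mm = profile_fwhm(prof_z$coord, prof_z$value) * 1e3,
    profiles = list(x = prof_x, z = prof_z),
    thermal = thermal,
    thermal_summary = summary(thermal)
  )
}

#' Pressure-amplitude line profile through the focal center
#'
#' Evaluates |P1| along one axis through the focal center at the requested
#' sampling, with the configured attenuation applied. Avoids materializing
#' the full fine acoustic volume when only line profiles are needed.
#'
#' @param spec a \code{\link{transducer_spec}}.
#' @param alpha_np absorption (Np/m).
#' @param attenuation \code{"axial"}, \code{"uniform"}, or \code{"none"}.
#' @param axis profile axis.
#' @param spacing sample spacing (m).
#' @param half_extent half-length of the profile (m).
#' @return List with \code{coord} and \code{value} (|P1| in Pa).
#' @export
pressure_axis_profile <- function(spec, alpha_np = 0,
                                  attenuation = c("axial", "uniform", "none"),
                                  axis = c("x", "y", "z"),
                                  spacing, half_extent) {
  attenuation <- match.arg(attenuation)
  axis <- match.arg(axis)
  s <- spacing * seq.int(-round(half_extent / spacing),
                         round(half_extent / spacing))
  zero <- numeric(length(s))
  p <- switch(axis,
    x = pressure_kernel(s, zero, zero, spec),
    y = pressure_kernel(zero, s, zero, spec),
    z = pressure_kernel(zero, zero, s, spec)
  )
  z_co <- if (axis == "z") s else zero
  att <- switch(attenuation,
    axial = exp(-alpha_np * (z_co + spec$focus_depth)),
    uniform = exp(-alpha_np * spec$focus_depth),
    none = 1
  )
  list(coord = s, value = Mod(p) * att)
}

preset_fig3 <- function(cfg, obj) {
  agent <- obj$agent
  Ts <- seq(agent$T_M - 3, agent$T_M + 3, by = 0.01)
  Q <- quantum_yield(Ts, agent)
  rec <- characterize_curve(Ts, Q)
  list(T = Ts, Q = Q, dQdT = yield_derivative(Ts, agent),
       agent = agent, recovered = rec)
}

preset_fig4 <- function(cfg, obj, scenario) {
  times <- preset_times(cfg)
  thermal <- preset_thermal(cfg, obj, times, grid_block = "dynamics")
  map <- nanoagent_map(thermal$grid, scenario, C0 = cfg$scenario$C0)
  series <- usf_signal(thermal, map, obj$agent, obj$geom, obj$optics_ex,
                       obj$optics_fl, obj$sd)
  vel <- usf_velocity(series)
  psf_times <- intersect(c(0.15, 0.4, 0.52, 0.71), times)
  maps <- lapply(psf_times, function(tp)
    surface_map(thermal, map, obj$agent, obj$geom, obj$optics_ex,
                obj$optics_fl, obj$sd, t = tp,
                raster_u = seq(-8e-3, 8e-3, by = 2e-3), normalize = TRUE))
  list(series = series, velocity = vel, surface_maps = maps,
       psf_times = psf_times)
}

preset_fig5 <- function(cfg, obj) {
  times <- preset_times(cfg)
  thermal <- preset_thermal(cfg, obj, times, grid_block = "dynamics")
  two_point_experiment(cfg$scenario$separation, thermal, obj$agent,
                       obj$geom, obj$optics_ex, obj$optics_fl, obj$sd,
                       axis = cfg$scenario$axis, C0 = cfg$scenario$C0)
}

preset_fig67 <- function(cfg, obj, which) {
  frame_times <- seq(0, 0.35, by = 0.05)
  # the velocity weights need neighbours around each reporting frame
  times <- preset_times(cfg)
  times <- times[times <= 0.4]
  thermal <- preset_thermal(cfg, obj, times, grid_block = "dynamics")
  placements <- c("top", "bottom", "side")
  mats <- lapply(placements, function(pl) {
    geom <- boundary_geometry(cfg$transducer$focus_depth, obj$optics_ex,
                              obj$optics_fl, orientation = pl,
                              sd_offset = cfg$geometry$sd_offset,
                              shared_ezb = cfg$geometry$shared_ezb)
    W <- sensitivity_kernel(thermal, obj$agent, geom, obj$optics_ex,
                            obj$optics_fl, obj$sd)
    normalize_sensitivity(W, "global")
  })
  names(mats) <- placements
  list(matrices = mats, which = which, frame_times = frame_times,
       all_times = times, grid = thermal$grid)
}

# ---------------------------------------------------------------------------

write_preset_outputs <- function(out, name, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(out$meta, file.path(out_dir, paste0(name, "_meta.json")),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(out$series)) {
    v <- out$velocity
    pk <- max(abs(out$series$phi))
    utils::write.csv(data.frame(
      t_s = out$series$t,
      phi_norm = if (pk > 0) out$series$phi / pk else out$series$phi,
      v_norm = if (max(abs(v$velocity)) > 0)
        v$velocity / max(abs(v$velocity)) else v$velocity,
      dT_focal_K = out$series$dT_focal
    ), file.path(out_dir, paste0(name, "_series.csv")), row.names = FALSE)
  }
  if (!is.null(out$thermal_summary))
    utils::write.csv(out$thermal_summary,
                     file.path(out_dir, paste0(name, "_thermal.csv")),
                     row.names = FALSE)
  if (!is.null(out$profiles)) {
    for (ax in names(out$profiles))
      utils::write.csv(data.frame(coordinate_m = out$profiles[[ax]]$coord,
                                  value = out$profiles[[ax]]$value),
                       file.path(out_dir, sprintf("%s_profile_%s.csv", name, ax)),
                       row.names = FALSE)
  }
  if (!is.null(out$surface_maps) && requireNamespace("tiff", quietly = TRUE)) {
    pages <- lapply(out$surface_maps, function(m) m$map / max(m$map, 1e-300))
    tiff::writeTIFF(pages, file.path(out_dir, paste0(name, "_psf.tiff")),
                    bits.per.sample = 32)
    jsonlite::write_json(list(times_s = out$psf_times,
                              u_m = out$surface_maps[[1]]$u,
                              v_m = out$surface_maps[[1]]$v),
                         file.path(out_dir, paste0(name, "_psf.tiff.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(out$thermal) && requireNamespace("tiff", quietly = TRUE))
    write_volume_tiff(out$thermal,
                      file.path(out_dir, paste0(name, "_dT.tiff")))
  if (!is.null(out$matrices)) {
    for (pl in names(out$matrices))
      write_sensitivity(out$matrices[[pl]], out$which, out$frame_times,
                        file.path(out_dir, sprintf("%s_%s", name, pl)))
  }
  invisible(out_dir)
}

# thermal snapshots as one multi-page 32-bit TIFF + JSON sidecar
write_volume_tiff <- function(thermal, path) {
  ctr <- grid_center(thermal$grid)
  pages <- lapply(thermal$dT, function(u) {
    sl <- u[, ctr[2], ]            # XZ plane through the focus
    sl / max(sl, 1e-300)           # writeTIFF expects [0, 1]
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  jsonlite::write_json(list(
    times_s = thermal$times,
    scale_K = vapply(thermal$dT, max, numeric(1)),
    dx_m = thermal$grid$dx, dz_m = thermal$grid$dz,
    plane = "XZ through focal center"
  ), paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# sensitivity frames as CSV (long format) + JSON metadata
write_sensitivity <- function(W, which, frame_times, stem) {
  keep <- match(round(frame_times, 10), round(W$times, 10))
  keep <- keep[!is.na(keep)]
  M <- if (which == "velocity") W$W_velocity else W$W_signal
  df <- data.frame(W$coords, M[, keep, drop = FALSE])
  names(df) <- c("x_m", "y_m", "z_m", sprintf("t_%g", W$times[keep]))
  utils::write.csv(df, paste0(stem, "_weights.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    sd_placement = W$sd_label, normalization = W$normalization,
    quantity = which, frame_times_s = W$times[keep]
  ), paste0(stem, "_weights.json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}
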