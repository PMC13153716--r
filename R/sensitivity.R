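#' Time-dependent sensitivity (weight) matrices via the signal kernel
#'
#' Computes the per-voxel, per-time contribution of a unit fluorophore
#' concentration to the detector signal (the Jacobian used in tomographic
#' reconstruction). Exploiting the linearity of the USF signal in the
#' concentration, the weight of voxel \eqn{j} at snapshot \eqn{t} is
#' \deqn{W_{sig}(j, t) = K \, [G_{ex}(r_j)(Q(T(r_j, t)) - Q(T_{BG}))
#'   G_{fl}(r_j, r_D) - (\mathrm{image\ term})] \, d\Omega,}
#' and the velocity weight is its time derivative (central differences).
#' Definitionally equivalent to scanning a single filled voxel through the
#' volume (\code{\link{sensitivity_scan}}), but evaluated in one pass.
#'
#' @param thermal a \code{\link{solve_bioheat}} result (independent of any
#'   concentration map).
#' @param agent a \code{\link{nanoagent_spec}}.
#' @param geom a \code{\link{boundary_geometry}}.
#' @param optics_ex,optics_fl \code{\link{optical_medium}} objects.
#' @param sd a \code{\link{sd_config}}.
#' @param voxels optional integer vector of linear voxel indices into the
#'   thermal grid; default all voxels.
#' @return Object of class \code{"sensitivity_matrix"} with matrices
#'   \code{W_signal} and \code{W_velocity} (voxels x snapshots), the voxel
#'   indices and coordinates, snapshot times, grid, and the geometry tag.
#' @export
sensitivity_kernel <- function(thermal, agent, geom, optics_ex, optics_fl,
                               sd = sd_config(), voxels = NULL) {
  stopifnot(inherits(thermal, "thermal_field"),
            inherits(agent, "nanoagent_spec"))
  grid <- thermal$grid
  if (is.null(voxels)) voxels <- seq_len(prod(grid$dim))
  co <- grid_coords(grid)[voxels, , drop = FALSE]
  ker <- usf_kernel_diff(co, geom, optics_ex, optics_fl)
  kd <- ker$direct - ker$image
  K <- usf_prefactor(optics_ex, optics_fl, sd)
  Q_bg <- quantum_yield(agent$T_BG, agent)
  nt <- length(thermal$times)
  W <- matrix(0, length(voxels), nt)
  for (i in seq_len(nt)) {
    Q <- quantum_yield(agent$T_BG + thermal$dT[[i]][voxels], agent)
    W[, i] <- K * grid$dV * (Q - Q_bg) * kd
  }
  Wv <- t(apply(W, 1, function(y) finite_diff(thermal$times, y)))
  if (nt < 3) Wv <- matrix(NA_real_, length(voxels), nt)
  structure(list(
    W_signal = W, W_velocity = Wv,
    times = thermal$times, voxels = voxels, coords = co, grid = grid,
    sd_label = geom$orientation, normalization = "raw"
  ), class = "sensitivity_matrix")
}

#' Sensitivity matrices by brute-force single-voxel scan
#'
#' Reference implementation of the sensitivity matrix: for every requested
#' voxel a concentration map with that single voxel filled at unit
#' concentration is built and the full USF signal computation is run. Slow;
#' intended for validating \code{\link{sensitivity_kernel}} on small
#' subgrids.
#'
#' @inheritParams sensitivity_kernel
#' @return A \code{"sensitivity_matrix"}, same layout as the kernel path.
#' @export
sensitivity_scan <- function(thermal, agent, geom, optics_ex, optics_fl,
                             sd = sd_config(), voxels = NULL) {
  grid <- thermal$grid
  if (is.null(voxels)) voxels <- seq_len(prod(grid$dim))
  nt <- length(thermal$times)
  W <- matrix(0, length(voxels), nt)
  for (j in seq_along(voxels)) {
    C <- array(0, grid$dim)
    C[voxels[j]] <- 1
    mp <- nanoagent_map(grid, "custom", C = C)
    W[j, ] <- usf_signal(thermal, mp, agent, geom, optics_ex, optics_fl, sd)$phi
  }
  Wv <- t(apply(W, 1, function(y) finite_diff(thermal$times, y)))
  if (nt < 3) Wv <- matrix(NA_real_, length(voxels), nt)
  structure(list(
    W_signal = W, W_velocity = Wv,
    times = thermal$times, voxels = voxels,
    coords = grid_coords(grid)[voxels, , drop = FALSE], grid = grid,
    sd_label = geom$orientation, normalization = "raw"
  ), class = "sensitivity_matrix")
}

#' @export
print.sensitivity_matrix <- function(x, ...) {
  cat(sprintf("USF sensitivity matrix (%s SD placement, %s normalization)\n",
              x$sd_label, x$normalization))
  cat(sprintf("  %d voxels x %d snapshots on [%g, %g] s\n",
              nrow(x$W_signal), length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  max |W_signal| = %.4g, max |W_velocity| = %.4g\n",
              max(abs(x$W_signal)), max(abs(x$W_velocity))))
  invisible(x)
}

#' Normalize a sensitivity matrix
#'
#' \code{"global"} scales signal and velocity weights each by their single
#' maximum absolute value over all voxels and times (preserving the growth
#' of sensitivity over time); \code{"per_frame"} scales each snapshot column
#' to unit maximum; \code{"raw"} returns physical units.
#'
#' @param x a \code{\link{sensitivity_kernel}} result.
#' @param mode normalization mode.
#' @return The rescaled \code{"sensitivity_matrix"}.
#' @export
normalize_sensitivity <- function(x, mode = c("global", "per_frame", "raw")) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "sensitivity_matrix"))
  if (x$normalization != "raw")
    stop("matrix is already normalized; start from the raw matrix")
  scale_mat <- function(W, mode) {
    if (mode == "raw") return(W)
    if (mode == "global") {
      m <- max(abs(W))
      return(if (m > 0) W / m else W)
    }
    apply(W, 2, function(col) {
      m <- max(abs(col)); if (m > 0) col / m else col
    })
  }
  x$W_signal <- scale_mat(x$W_signal, mode)
  x$W_velocity <- scale_mat(x$W_velocity, mode)
  x$normalization <- mode
  x
}

#' Support fraction and ring thickness of sensitivity frames
#'
#' For each snapshot, measures how concentrated the weight distribution is:
#' the fraction of voxels whose absolute weight reaches \code{level} times
#' the frame maximum, and the thickness of the above-level region along the
#' +X and +Z rays from the focal center. The late-time velocity weights
#' form a shell around the saturated core; the ray thickness measures the
#' shell width per axis, thresholded against the maximum along that ray so
#' the measurement is insensitive to the strong depth weighting of the
#' optical kernels.
#'
#' @param x a \code{\link{sensitivity_kernel}} result covering the full
#'   thermal grid (the rays must be present in the voxel subset).
#' @param level threshold as a fraction of the frame maximum, in (0, 1).
#' @param which use the signal or the velocity weights.
#' @return Data frame with one row per snapshot: \code{time},
#'   \code{support_fraction}, \code{ring_x}, \code{ring_z} (m), and
#'   \code{empty} flag.
#' @export
support_metrics <- function(x, level = 0.5, which = c("signal", "velocity")) {
  which <- match.arg(which)
  stopifnot(inherits(x, "sensitivity_matrix"), level > 0, level < 1)
  W <- if (which == "signal") x$W_signal else x$W_velocity
  grid <- x$grid
  full <- length(x$voxels) == prod(grid$dim)
  if (!full)
    stop("support metrics need a matrix over the full thermal grid")
  ctr <- grid_center(grid)
  nxy <- grid$dim[1] * grid$dim[2]
  # linear indices of the +X and +Z rays from the focal center
  ray_x <- (ctr[1]:grid$dim[1]) + grid$dim[1] * (ctr[2] - 1L) +
    nxy * (ctr[3] - 1L)
  ray_z <- ctr[1] + grid$dim[1] * (ctr[2] - 1L) +
    nxy * ((ctr[3]:grid$dim[3]) - 1L)
  out <- data.frame(time = x$times, support_fraction = NA_real_,
                    ring_x = NA_real_, ring_z = NA_real_, empty = FALSE)
  for (i in seq_along(x$times)) {
    w <- abs(W[, i])
    fm <- max(w)
    if (fm == 0) {
      out$support_fraction[i] <- 0
      out$ring_x[i] <- out$ring_z[i] <- 0
      out$empty[i] <- TRUE
      next
    }
    out$support_fraction[i] <- mean(w >= level * fm)
    wx <- w[ray_x]
    wz <- w[ray_z]
    out$ring_x[i] <- if (max(wx) > 0) sum(wx >= level * max(wx)) * grid$dx else 0
    out$ring_z[i] <- if (max(wz) > 0) sum(wz >= level * max(wz)) * grid$dz else 0
  }
  out
}
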