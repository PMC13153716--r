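#' Cartesian simulation grid centred on the ultrasound focus
#'
#' Builds a regular Cartesian grid whose origin coincides with the focal
#' center of the ultrasound beam. The +Z axis points along the ultrasound
#' propagation direction (top to bottom). Sample counts per axis are always
#' odd so the origin itself is a grid node.
#'
#' @param dx,dy,dz voxel spacings (m).
#' @param Lx,Ly,Lz half-extents (m); the grid spans \code{[-L, +L]} per axis,
#'   rounded to an integer number of spacings.
#' @return An object of class \code{"usf_grid"} with axis coordinate vectors
#'   \code{x}, \code{y}, \code{z}, spacings, dimensions \code{dim}, and the
#'   voxel volume \code{dV} (m^3).
#' @examples
#' g <- usf_grid(50e-6, 50e-6, 175e-6, 3e-3, 3e-3, 7e-3)
#' g$dim
#' @export
usf_grid <- function(dx, dy, dz, Lx, Ly, Lz) {
  sp <- c(dx = dx, dy = dy, dz = dz)
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("grid spacings must be positive and finite")
  if (any(c(Lx, Ly, Lz) < sp))
    stop("half-extents must be at least one voxel spacing")
  ax <- function(d, L) d * seq.int(-round(L / d), round(L / d))
  g <- structure(list(
    x = ax(dx, Lx), y = ax(dy, Ly), z = ax(dz, Lz),
    dx = dx, dy = dy, dz = dz,
    dV = dx * dy * dz
  ), class = "usf_grid")
  g$dim <- c(length(g$x), length(g$y), length(g$z))
  g
}

#' @export
print.usf_grid <- function(x, ...) {
  cat("USF Cartesian grid (origin at focal center, +Z = propagation)\n")
  cat(sprintf("  dims    : %d x %d x %d voxels (%s total)\n",
              x$dim[1], x$dim[2], x$dim[3],
              format(prod(x$dim), big.mark = ",")))
  cat(sprintf("  spacing : %.4g x %.4g x %.4g mm\n",
              x$dx * 1e3, x$dy * 1e3, x$dz * 1e3))
  cat(sprintf("  extent  : [%.3g, %.3g] x [%.3g, %.3g] x [%.3g, %.3g] mm\n",
              min(x$x) * 1e3, max(x$x) * 1e3, min(x$y) * 1e3, max(x$y) * 1e3,
              min(x$z) * 1e3, max(x$z) * 1e3))
  invisible(x)
}

# index of the origin node along each axis
grid_center <- function(grid) (grid$dim + 1L) / 2L

# n x 3 matrix of all voxel coordinates in array order (x fastest)
grid_coords <- function(grid) {
  cbind(
    x = rep(grid$x, times = grid$dim[2] * grid$dim[3]),
    y = rep(rep(grid$y, each = grid$dim[1]), times = grid$dim[3]),
    z = rep(grid$z, each = grid$dim[1] * grid$dim[2])
  )
}

#' Full width at half maximum of a sampled profile
#'
#' Measures the FWHM of a non-negative 1-D profile with a unique interior
#' peak region, locating the two half-maximum crossings by linear
#' interpolation between the bracketing samples.
#'
#' @param coord sample coordinates (m), strictly increasing.
#' @param value profile values, non-negative.
#' @return FWHM in the units of \code{coord}.
#' @examples
#' x <- seq(-5, 5, by = 0.01)
#' profile_fwhm(x, exp(-x^2 / 2))  # ~ 2*sqrt(2*log(2))
#' @export
profile_fwhm <- function(coord, value) {
  stopifnot(length(coord) == length(value), length(coord) >= 3)
  if (any(diff(coord) <= 0)) stop("'coord' must be strictly increasing")
  im <- which.max(value)
  half <- value[im] / 2
  if (im == 1L || im == length(value))
    stop("profile not resolved within extent: peak lies on the boundary")
  left <- which(value[seq_len(im)] <= half)
  right <- which(value[im:length(value)] <= half)
  if (length(left) == 0L || length(right) == 0L)
    stop("profile not resolved within extent: half maximum never crossed")
  li <- max(left)
  ri <- im - 1L + min(right)
  xl <- coord[li] + (half - value[li]) / (value[li + 1L] - value[li]) *
    (coord[li + 1L] - coord[li])
  xr <- coord[ri - 1L] + (half - value[ri - 1L]) / (value[ri] - value[ri - 1L]) *
    (coord[ri] - coord[ri - 1L])
  xr - xl
}

# extract an axis line through the grid center from a 3-D array
center_profile <- function(arr, grid, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  ctr <- grid_center(grid)
  switch(axis,
    x = list(coord = grid$x, value = arr[, ctr[2], ctr[3]]),
    y = list(coord = grid$y, value = arr[ctr[1], , ctr[3]]),
    z = list(coord = grid$z, value = arr[ctr[1], ctr[2], ])
  )
}
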