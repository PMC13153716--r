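#' Thermosensitive nanoagent switching parameters
#'
#' Describes the temperature-gated fluorescence of a USF nanoagent: baseline
#' quantum yield \code{Q0}, on-to-off ratio \code{R0}, and the switching
#' transition, given either as the threshold/saturation pair
#' \code{(T_th, T_sa)} or as the midpoint/width pair \code{(T_M, sigma)}.
#' The two parametrizations are related by
#' \eqn{T_M = (T_{th} + T_{sa}) / 2}, \eqn{T_{BW} = T_{sa} - T_{th}}, and
#' \eqn{\sigma = T_{BW} / (2 \sqrt{2 \ln 2})} (the transition bandwidth is
#' the FWHM of the Gaussian derivative of the yield curve).
#'
#' @param Q0 baseline quantum yield at the background temperature.
#' @param R0 on-to-off fluorescence ratio; must satisfy
#'   \eqn{1 < R_0 < 1/Q_0} so the yield stays within (0, 1].
#' @param T_th,T_sa switch-on threshold and saturation temperature (C).
#' @param T_M,sigma transition midpoint (C) and Gaussian width (C);
#'   alternative to \code{T_th}/\code{T_sa}.
#' @param T_BG tissue background temperature (C).
#' @return Object of class \code{"nanoagent_spec"} with all of \code{Q0},
#'   \code{R0}, \code{T_th}, \code{T_sa}, \code{T_M}, \code{T_BW},
#'   \code{sigma}, \code{T_BG}.
#' @examples
#' ag <- nanoagent_spec(Q0 = 0.05, R0 = 2.6, T_M = 38.7, sigma = 1 / (3 * sqrt(2)))
#' c(ag$T_th, ag$T_sa)   # ~38.42, ~38.98
#' @export
nanoagent_spec <- function(Q0 = 0.05, R0 = 2.6,
                           T_th = NULL, T_sa = NULL,
                           T_M = NULL, sigma = NULL, T_BG = 37) {
  stopifnot(Q0 > 0)
  if (R0 <= 1 || R0 >= 1 / Q0)
    stop("R0 must satisfy 1 < R0 < 1/Q0 for a physically meaningful yield")
  fwhm_c <- 2 * sqrt(2 * log(2))
  if (!is.null(T_th) && !is.null(T_sa)) {
    if (T_sa <= T_th) stop("T_sa must exceed T_th")
    T_M <- (T_th + T_sa) / 2
    T_BW <- T_sa - T_th
    sigma <- T_BW / fwhm_c
  } else if (!is.null(T_M) && !is.null(sigma)) {
    stopifnot(sigma > 0)
    T_BW <- fwhm_c * sigma
    T_th <- T_M - T_BW / 2
    T_sa <- T_M + T_BW / 2
  } else {
    stop("provide either (T_th, T_sa) or (T_M, sigma)")
  }
  structure(list(
    Q0 = Q0, R0 = R0, T_th = T_th, T_sa = T_sa,
    T_M = T_M, T_BW = T_BW, sigma = sigma, T_BG = T_BG
  ), class = "nanoagent_spec")
}

#' @export
print.nanoagent_spec <- function(x, ...) {
  cat("USF nanoagent switching curve\n")
  cat(sprintf("  Q0 = %g, R0 = %g (on yield %g)\n", x$Q0, x$R0, x$Q0 * x$R0))
  cat(sprintf("  T_th = %.3f C, T_sa = %.3f C, T_M = %.3f C\n",
              x$T_th, x$T_sa, x$T_M))
  cat(sprintf("  T_BW = %.3f C (sigma = %.4f C), T_BG = %g C\n",
              x$T_BW, x$sigma, x$T_BG))
  invisible(x)
}

#' Temperature-dependent quantum yield
#'
#' Smooth step model of the fluorescence quantum yield,
#' \deqn{Q(T) = Q_0 \{1 + [(R_0 - 1)/2] \,
#'   \mathrm{erfc}[-(T - T_M) / (\sqrt{2} \sigma)]\},}
#' rising from \eqn{Q_0} below the transition to \eqn{Q_0 R_0} above it.
#' Applied elementwise to vectors or arrays.
#'
#' @param T temperature (C), any numeric shape.
#' @param spec a \code{\link{nanoagent_spec}}.
#' @return Quantum yield with the shape of \code{T}.
#' @examples
#' ag <- nanoagent_spec()
#' quantum_yield(ag$T_M, ag)  # Q0 * (1 + (R0 - 1)/2)
#' @export
quantum_yield <- function(T, spec) {
  stopifnot(inherits(spec, "nanoagent_spec"))
  # erfc(-(T - T_M)/(sqrt(2) sigma)) == 2 * pnorm((T - T_M)/sigma)
  spec$Q0 * (1 + (spec$R0 - 1) * stats::pnorm((T - spec$T_M) / spec$sigma))
}

#' Temperature derivative of the quantum yield
#'
#' \deqn{dQ/dT = Q_0 (R_0 - 1) \frac{1}{\sqrt{2\pi}\sigma}
#'   \exp[-((T - T_M)/(\sqrt{2}\sigma))^2],}
#' a Gaussian centred at \eqn{T_M} with standard deviation \eqn{\sigma};
#' its FWHM is the transition bandwidth \eqn{T_{BW}}.
#'
#' @inheritParams quantum_yield
#' @return dQ/dT (1/C) with the shape of \code{T}.
#' @export
yield_derivative <- function(T, spec) {
  stopifnot(inherits(spec, "nanoagent_spec"))
  spec$Q0 * (spec$R0 - 1) *
    stats::dnorm((T - spec$T_M) / spec$sigma) / spec$sigma
}

#' Extract switching parameters from a measured fluorescence curve
#'
#' Numerically differentiates a measured fluorescence-versus-temperature
#' curve and reads the transition off the derivative: \code{T_th} and
#' \code{T_sa} are the lower and upper half-maximum temperatures of the
#' derivative peak (linear interpolation between samples), \code{T_M} their
#' midpoint, \code{T_BW} their difference, and
#' \eqn{\sigma = T_{BW} / (2\sqrt{2 \ln 2})}. Affine rescaling of the
#' fluorescence axis (gain or offset) leaves all recovered temperatures
#' unchanged.
#'
#' @param T_samples temperatures (C), strictly increasing, dense enough to
#'   resolve the transition.
#' @param F_samples fluorescence strength (arbitrary units).
#' @return List with \code{T_th}, \code{T_sa}, \code{T_M}, \code{T_BW},
#'   \code{sigma} (all C).
#' @export
characterize_curve <- function(T_samples, F_samples) {
  stopifnot(length(T_samples) == length(F_samples), length(T_samples) >= 10)
  if (any(diff(T_samples) <= 0))
    stop("temperature samples must be strictly increasing")
  n <- length(T_samples)
  # centered differences on the interior, one-sided at the ends
  dF <- numeric(n)
  dF[2:(n - 1)] <- (F_samples[3:n] - F_samples[1:(n - 2)]) /
    (T_samples[3:n] - T_samples[1:(n - 2)])
  dF[1] <- (F_samples[2] - F_samples[1]) / (T_samples[2] - T_samples[1])
  dF[n] <- (F_samples[n] - F_samples[n - 1]) / (T_samples[n] - T_samples[n - 1])
  im <- which.max(dF)
  if (im == 1L || im == n || dF[im] <= 0)
    stop("no transition found: derivative has no interior peak")
  half <- dF[im] / 2
  left <- which(dF[seq_len(im)] <= half)
  right <- which(dF[im:n] <= half)
  if (length(left) == 0L || length(right) == 0L)
    stop("no transition found: half maximum of the derivative not bracketed")
  li <- max(left)
  ri <- im - 1L + min(right)
  T_th <- T_samples[li] + (half - dF[li]) / (dF[li + 1L] - dF[li]) *
    (T_samples[li + 1L] - T_samples[li])
  T_sa <- T_samples[ri - 1L] + (half - dF[ri - 1L]) / (dF[ri] - dF[ri - 1L]) *
    (T_samples[ri] - T_samples[ri - 1L])
  list(
    T_th = T_th, T_sa = T_sa, T_M = (T_th + T_sa) / 2,
    T_BW = T_sa - T_th, sigma = (T_sa - T_th) / (2 * sqrt(2 * log(2)))
  )
}
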