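# Boundary data on the electrode plane: electrode values plus the cubic
# Dirichlet approximation of the inter-electrode (gap) potential.

#' Cubic approximation of the inter-electrode boundary potential
#'
#' With `s = (x* - 1/2) / (1/2 - w/L)` (so `s = -1` at the powered-electrode
#' edge and `s = +1` at the grounded-electrode edge),
#' \deqn{\varphi(x^*, 1) = \frac{V_{rms}}{\pi}
#'   \left[\frac{\pi}{2} - C s - \left(\frac{\pi}{2} - C\right) s^3\right].}
#' The profile is continuous with the electrode potentials at both edges
#' (`V_rms` at `s = -1`, `0` at `s = +1`) for every `C`, antisymmetric about
#' the gap midpoint in the sense `phi(x) + phi(1 - x) = V_rms`, and linear
#' in `C`, which makes the least-squares calibration of `C` closed-form
#' ([fit_gap_constant()]).  It is the two-term odd-polynomial approximation
#' of the exact conformal-map gap potential
#' `(V_rms/pi) (pi/2 - asin s)` ([gap_reference_halfspace()]).
#'
#' @param x_star dimensionless coordinate(s), strictly inside
#'   `(w/L, 1 - w/L)`.
#' @param geometry a [device_geometry()].
#' @param drive a [drive_settings()].
#' @param gap a [gap_approximation()].
#' @return potential (V), vectorised over `x_star`.
#' @export
gap_potential <- function(x_star, geometry, drive,
                          gap = gap_approximation()) {
  g <- geometry$g
  if (any(x_star <= g) || any(x_star >= 1 - g))
    stop("x_star must lie strictly inside the gap (w/L, 1 - w/L)")
  .gap_profile(x_star, g, drive$Vrms, gap$C)
}

.gap_profile <- function(x_star, g, Vrms, C) {
  s <- (x_star - 0.5) / (0.5 - g)
  (Vrms / pi) * (pi / 2 - C * s - (pi / 2 - C) * s^3)
}

#' Boundary potential along the whole electrode plane
#'
#' Piecewise Dirichlet data at `y* = 1`: `V_rms` on the powered finger
#' `[0, w/L]`, the cubic [gap_potential()] on the gap, and `0` on the
#' grounded finger `[1 - w/L, 1]`.
#'
#' @inheritParams gap_potential
#' @param x_star dimensionless coordinate(s) in `[0, 1]`.
#' @return potential (V), vectorised.
#' @export
top_boundary_profile <- function(x_star, geometry, drive,
                                 gap = gap_approximation()) {
  if (any(x_star < 0) || any(x_star > 1)) stop("x_star must lie in [0, 1]")
  g <- geometry$g
  out <- numeric(length(x_star))
  out[x_star <= g] <- drive$Vrms
  inside <- x_star > g & x_star < 1 - g
  out[inside] <- .gap_profile(x_star[inside], g, drive$Vrms, gap$C)
  out
}

#' Conformal-map gap potential of an isolated coplanar electrode pair
#'
#' Exact boundary-layer reference for the gap potential: for two coplanar
#' half-plane electrodes at `V_rms` and `0` separated by a gap, the
#' potential on the gap line is
#' `phi = (V_rms/pi) (pi/2 - asin s)` with `s` the gap-normalised
#' coordinate of [gap_potential()].  This is the canonical reference
#' profile against which the cubic constant `C` is calibrated; fitting the
#' cubic family to it by linear least squares gives `C = 0.754718`.
#'
#' @inheritParams gap_potential
#' @return potential (V), vectorised over `x_star`.
#' @export
gap_reference_halfspace <- function(x_star, geometry, drive) {
  g <- geometry$g
  if (any(x_star <= g) || any(x_star >= 1 - g))
    stop("x_star must lie strictly inside the gap (w/L, 1 - w/L)")
  s <- (x_star - 0.5) / (0.5 - g)
  (drive$Vrms / pi) * (pi / 2 - asin(s))
}
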