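# Device geometry, drive settings and the gap-profile constant.

#' Interdigitated-electrode device geometry
#'
#' The 2D cross-section model spans one half-period of the electrode array:
#' from the centre line of a powered finger (`x* = 0`) to the centre line of
#' the adjacent grounded finger (`x* = 1`).  `L` is the centre-to-centre
#' pitch of adjacent fingers, `2w` the finger width, `d = L - 2w` the
#' inter-electrode spacing and `H` the channel height (electrode plane at
#' `y* = 1`, grounded lid at `y* = 0`).  Physical coordinates are
#' `x = L x*`, `y = H y*`.
#'
#' @param H channel height (m).
#' @param w electrode half-width (m).
#' @param L finger pitch (m).  Give exactly one of `L` and `d`.
#' @param d electrode spacing (m), `d = L - 2w`.
#' @return An object of class `"device_geometry"` with fields `L`, `H`, `w`,
#'   `d` and the dimensionless ratios `g = w/L` and `HL = H/L`.
#' @examples
#' device_geometry(H = 500e-6, w = 25e-6, d = 50e-6)   # Type A
#' @export
device_geometry <- function(H, w, L = NULL, d = NULL) {
  if (is.null(L) == is.null(d))
    stop("give exactly one of `L` (pitch) or `d` (spacing)")
  if (is.null(L)) L <- 2 * w + d
  d_derived <- L - 2 * w
  if (!is.null(d) && abs(d - d_derived) > 1e-12 * L)
    stop("inconsistent geometry: d != L - 2w")
  if (!all(is.finite(c(L, H, w))) || H <= 0 || w <= 0)
    stop("H and w must be positive")
  if (d_derived <= 0) stop("need 0 < 2w < L (positive electrode spacing)")
  structure(
    list(L = L, H = H, w = w, d = d_derived, g = w / L, HL = H / L),
    class = "device_geometry")
}

#' @export
print.device_geometry <- function(x, ...) {
  cat(sprintf(
    "Device geometry: 2w = %g um, d = %g um (L = %g um), H = %g um\n",
    2e6 * x$w, 1e6 * x$d, 1e6 * x$L, 1e6 * x$H))
  cat(sprintf("  aspect ratios: H/L = %g, w/L = %g\n", x$HL, x$g))
  invisible(x)
}

#' AC drive settings
#'
#' @param Vrms effective (root-mean-square) drive voltage (V).  Give exactly
#'   one of `Vrms` and `Vpp`; a sinusoidal peak-to-peak drive converts as
#'   `Vrms = Vpp / (2 sqrt(2))`.
#' @param Vpp peak-to-peak drive voltage (V).
#' @param f field frequency (Hz).
#' @return An object of class `"drive_settings"` with fields `Vrms`, `f`.
#' @examples
#' drive_settings(Vpp = 10, f = 8.5e6)   # Vrms = 5/sqrt(2)
#' @export
drive_settings <- function(Vrms = NULL, Vpp = NULL, f) {
  if (is.null(Vrms) == is.null(Vpp))
    stop("give exactly one of `Vrms` or `Vpp`")
  if (is.null(Vrms)) Vrms <- Vpp / (2 * sqrt(2))
  if (!is.finite(Vrms) || Vrms <= 0) stop("drive voltage must be positive")
  if (!is.finite(f) || f <= 0) stop("frequency must be positive")
  structure(list(Vrms = Vrms, f = f), class = "drive_settings")
}

#' @export
print.drive_settings <- function(x, ...) {
  cat(sprintf("Drive: Vrms = %.6g V, f = %g Hz\n", x$Vrms, x$f))
  invisible(x)
}

#' Cubic gap-profile constant
#'
#' The inter-electrode (gap) boundary potential is approximated by the cubic
#' profile of [gap_potential()] with a single dimensionless constant `C`.
#' `C = pi/2` degenerates to the linear interpolant; the calibrated default
#' 0.75480 is the least-squares optimum against the conformal-map solution
#' for a coplanar electrode gap (see [fit_gap_constant()]).
#'
#' @param C dimensionless constant, `0 < C < pi/2`.
#' @return An object of class `"gap_approximation"`.
#' @export
gap_approximation <- function(C = 0.75480) {
  if (!is.finite(C) || C <= 0 || C >= pi / 2)
    stop("C must lie in (0, pi/2)")
  structure(list(C = C), class = "gap_approximation")
}

#' Device presets
#'
#' The three fabricated electrode layouts: (width `2w` : spacing `d`) of
#' (50:50), (50:75) and (75:50) micrometres, all with a 500 um channel, a
#' 10 Vpp drive at 8.5 MHz, and the standard low-conductivity sugar medium
#' (`eps_l = 6.9e-10` F/m, `sigma_l = 1e-3` S/m) with 15 um cells at
#' `Re(beta) = 0.98`.
#'
#' @param type `"A"`, `"B"` or `"C"`.
#' @return A list with elements `geometry`, `drive`, `medium`, `d_c`,
#'   `re_beta`, `prefactor`, `gap` and `n_terms`.
#' @examples
#' p <- device_preset("A")
#' p$geometry$HL   # 5
#' @export
device_preset <- function(type = c("A", "B", "C")) {
  type <- match.arg(type)
  dims <- switch(type,
    A = c(width = 50e-6, spacing = 50e-6),
    B = c(width = 50e-6, spacing = 75e-6),
    C = c(width = 75e-6, spacing = 50e-6))
  geometry <- device_geometry(H = 500e-6, w = dims[["width"]] / 2,
                              d = dims[["spacing"]])
  medium <- medium_properties(epsilon = 6.9e-10, sigma = 1e-3)
  list(geometry = geometry,
       drive = drive_settings(Vpp = 10, f = 8.5e6),
       medium = medium,
       d_c = 15e-6,
       re_beta = 0.98,
       prefactor = dep_prefactor(medium, 15e-6, 0.98),
       gap = gap_approximation(),
       n_terms = 10000L)
}
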