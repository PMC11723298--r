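# Clausius-Mossotti factor and DEP force prefactor.

#' Suspension medium dielectric properties
#'
#' @param epsilon absolute electric permittivity of the solution (F/m).
#'   Give either `epsilon` or `epsilon_r`.
#' @param sigma electric conductivity of the solution (S/m), `>= 0`.
#' @param epsilon_r relative permittivity; converted with [EPSILON_0].
#'
#' @return An object of class `"dep_medium"` with fields `epsilon_l`,
#'   `sigma_l` and the charge-relaxation time `tau_l = epsilon_l/sigma_l`
#'   (`Inf` for a non-conducting medium).
#' @examples
#' medium_properties(epsilon = 6.9e-10, sigma = 1e-3)
#' @export
medium_properties <- function(epsilon = NULL, sigma, epsilon_r = NULL) {
  epsilon <- .resolve_permittivity(epsilon, epsilon_r)
  stopifnot(is.numeric(sigma), length(sigma) == 1L, is.finite(sigma))
  if (epsilon <= 0) stop("medium permittivity must be positive")
  if (sigma < 0) stop("medium conductivity must be non-negative")
  structure(
    list(epsilon_l = epsilon, sigma_l = sigma,
         tau_l = if (sigma > 0) epsilon / sigma else Inf),
    class = "dep_medium")
}

#' Single-shell cell dielectric model
#'
#' A live cell is represented as a homogeneous sphere of effective interior
#' permittivity/conductivity wrapped in a thin membrane of capacitance per
#' unit area `c_m`; the membrane conductance is neglected.
#'
#' @param diameter spherical cell diameter (m).
#' @param c_membrane membrane capacitance per area (F/m^2).
#' @param epsilon effective absolute permittivity of the cell interior (F/m);
#'   give either `epsilon` or `epsilon_r`.
#' @param sigma effective conductivity of the cell interior (S/m), `> 0`.
#' @param epsilon_r relative interior permittivity.
#'
#' @return An object of class `"dep_cell"` with fields `d_c`, `c_m`,
#'   `epsilon_c`, `sigma_c` and the derived time constants
#'   `tau_c = epsilon_c/sigma_c` and `tau_c_star = c_m d_c / (2 sigma_c)`.
#' @examples
#' cell_model(diameter = 15e-6, c_membrane = 0.01, epsilon_r = 50, sigma = 0.5)
#' @export
cell_model <- function(diameter, c_membrane, epsilon = NULL, sigma,
                       epsilon_r = NULL) {
  epsilon <- .resolve_permittivity(epsilon, epsilon_r)
  vals <- c(diameter, c_membrane, epsilon, sigma)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all cell parameters must be positive and finite")
  structure(
    list(d_c = diameter, c_m = c_membrane,
         epsilon_c = epsilon, sigma_c = sigma,
         tau_c = epsilon / sigma,
         tau_c_star = c_membrane * diameter / (2 * sigma)),
    class = "dep_cell")
}

.resolve_permittivity <- function(epsilon, epsilon_r) {
  if (is.null(epsilon) == is.null(epsilon_r))
    stop("give exactly one of `epsilon` (F/m) or `epsilon_r` (relative)")
  if (is.null(epsilon)) epsilon_r * EPSILON_0 else epsilon
}

#' @export
print.dep_medium <- function(x, ...) {
  cat("Suspension medium: epsilon_l =", format(x$epsilon_l),
      "F/m, sigma_l =", format(x$sigma_l), "S/m",
      "(tau_l =", format(x$tau_l), "s)\n")
  invisible(x)
}

#' @export
print.dep_cell <- function(x, ...) {
  cat("Single-shell cell: d_c =", format(x$d_c * 1e6), "um,",
      "c_m =", format(x$c_m), "F/m^2,\n  epsilon_c =", format(x$epsilon_c),
      "F/m, sigma_c =", format(x$sigma_c), "S/m\n")
  invisible(x)
}

#' Complex permittivity of a lossy dielectric
#'
#' Uses the physics sign convention `eps* = eps + sigma/(j omega)`,
#' i.e. `eps - j sigma/omega` (the imaginary part is negative for a
#' conducting medium).  Many engineering texts use the conjugate; the
#' Clausius-Mossotti factor below is consistent with this convention.
#'
#' @param epsilon permittivity (F/m).
#' @param sigma conductivity (S/m).
#' @param omega angular frequency (rad/s), `> 0`.
#' @return complex permittivity (F/m), vectorised over `omega`.
#' @export
complex_permittivity <- function(epsilon, sigma, omega) {
  if (any(!is.finite(omega)) || any(omega <= 0))
    stop("omega must be positive and finite")
  complex(real = epsilon, imaginary = -sigma / omega)
}

#' Two-phase Clausius-Mossotti factor
#'
#' `beta = (eps_p* - eps_m*) / (eps_p* + 2 eps_m*)` for a homogeneous
#' spherical particle `p` in a medium `m`.  `Re(beta)` lies in
#' `[-1/2, 1]` for passive materials; positive values give positive DEP
#' (attraction towards strong-field regions).
#'
#' @param eps_p complex permittivity of the particle (F/m).
#' @param eps_m complex permittivity of the medium (F/m).
#' @return complex CM factor, vectorised.
#' @export
cm_factor <- function(eps_p, eps_m) {
  den <- eps_p + 2 * eps_m
  if (any(abs(den) == 0)) stop("vanishing denominator in CM factor")
  (eps_p - eps_m) / den
}

#' Effective complex permittivity of a membrane-covered cell
#'
#' Thin-shell limit of the single-shell model: the membrane acts as a
#' capacitance `c_m` per area in series with the cell interior, giving
#' `eps_cell* = c_m R eps_i* / (c_m R + eps_i*)` with `R = d_c/2`.
#'
#' @param cell a [cell_model()] object.
#' @param omega angular frequency (rad/s).
#' @return complex permittivity (F/m), vectorised over `omega`.
#' @export
cell_permittivity <- function(cell, omega) {
  eps_i <- complex_permittivity(cell$epsilon_c, cell$sigma_c, omega)
  cmR <- cell$c_m * cell$d_c / 2
  cmR * eps_i / (cmR + eps_i)
}

#' Single-shell Clausius-Mossotti factor
#'
#' Closed time-constant form of the CM factor for a membrane-covered cell,
#' derived from the thin-shell model (see [cell_permittivity()]).  With
#' `s = 1/(j omega)` and the four time constants
#' `tau_c* = c_m d_c/(2 sigma_c)`, `tau_c = epsilon_c/sigma_c`,
#' `tau_l* = c_m d_c/(2 sigma_l)`, `tau_l = epsilon_l/sigma_l`:
#' \deqn{\beta =
#'  \frac{\omega^2(\tau_c^*\tau_l + \tau_l\tau_c - \tau_l^*\tau_c)
#'        + j\omega(\tau_l^* - \tau_c^* - \tau_l - \tau_c) - 1}
#'       {-\omega^2(\tau_l^*\tau_c + 2\tau_l\tau_c^* + 2\tau_l\tau_c)
#'        + j\omega(\tau_l^* + 2\tau_c^* + 2\tau_l + 2\tau_c) + 2}}
#' The low-frequency limit is `-1/2` (an insulating membrane screens the
#' interior) and the high-frequency limit is the bare dielectric contrast
#' `(eps_c - eps_l)/(eps_c + 2 eps_l)`.
#'
#' The identical value is obtained by `cm_factor(cell_permittivity(cell,
#' w), complex_permittivity(eps_l, sigma_l, w))`; the two routes serve as
#' mutual cross-checks in the test suite.
#'
#' @param cell a [cell_model()] object.
#' @param medium a [medium_properties()] object with `sigma_l > 0`.
#' @param f field frequency (Hz), `> 0`; vectorised.
#' @return complex CM factor.
#' @examples
#' cl <- cell_model(15e-6, 0.01, epsilon_r = 50, sigma = 0.5)
#' md <- medium_properties(epsilon = 6.9e-10, sigma = 1e-3)
#' Re(cm_single_shell(cl, md, 8.5e6))
#' @export
cm_single_shell <- function(cell, medium, f) {
  if (any(!is.finite(f)) || any(f <= 0)) stop("frequency must be positive")
  if (medium$sigma_l <= 0)
    stop("single-shell form requires a conducting medium (sigma_l > 0)")
  w <- 2 * pi * f
  tcs <- cell$tau_c_star
  tc <- cell$tau_c
  tls <- cell$c_m * cell$d_c / (2 * medium$sigma_l)
  tl <- medium$tau_l
  num <- w^2 * (tcs * tl + tl * tc - tls * tc) +
    1i * w * (tls - tcs - tl - tc) - 1
  den <- -w^2 * (tls * tc + 2 * tl * tcs + 2 * tl * tc) +
    1i * w * (tls + 2 * tcs + 2 * tl + 2 * tc) + 2
  num / den
}

#' Frequency spectrum of the Clausius-Mossotti factor
#'
#' @param cell a [cell_model()] object.
#' @param medium a [medium_properties()] object.
#' @param frequencies strictly increasing positive frequency grid (Hz);
#'   default 400 log-spaced points over 1 kHz--1 GHz.
#' @return A data frame of class `"cm_spectrum"` with columns `frequency`,
#'   `re_beta`, `im_beta` and attribute `beta` (the complex values).
#' @export
cm_spectrum <- function(cell, medium,
                        frequencies = 10^seq(3, 9, length.out = 400)) {
  if (length(frequencies) < 1L) stop("empty frequency grid")
  if (any(diff(frequencies) <= 0))
    stop("frequencies must be strictly increasing")
  beta <- cm_single_shell(cell, medium, frequencies)
  out <- data.frame(frequency = frequencies,
                    re_beta = Re(beta), im_beta = Im(beta))
  attr(out, "beta") <- beta
  class(out) <- c("cm_spectrum", "data.frame")
  out
}

#' @export
plot.cm_spectrum <- function(x, ...) {
  graphics::plot(x$frequency, x$re_beta, type = "l", log = "x",
                 xlab = "frequency (Hz)", ylab = "Re(beta)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Frequency maximising the real part of the CM factor
#'
#' Coarse 200-point log-frequency scan followed by golden-section refinement
#' ([stats::optimize()]) on the bracketing interval.  Ties on the coarse
#' scan are broken towards the lowest frequency.
#'
#' @param cell,medium see [cm_single_shell()].
#' @param f_range numeric length-2, `0 < f_lo < f_hi` (Hz).
#' @param tol relative tolerance on the returned frequency.
#' @return frequency (Hz) maximising `Re(beta)` over the range.
#' @export
cm_peak_frequency <- function(cell, medium, f_range = c(1e3, 1e9),
                              tol = 1e-4) {
  if (length(f_range) != 2L || !all(is.finite(f_range)) ||
      f_range[1] <= 0 || f_range[2] <= f_range[1])
    stop("f_range must satisfy 0 < f_lo < f_hi")
  lf <- seq(log(f_range[1]), log(f_range[2]), length.out = 200)
  rb <- Re(cm_single_shell(cell, medium, exp(lf)))
  i <- which.max(rb)            # first maximum = lowest-frequency tie-break
  if (rb[i] - min(rb) < .Machine$double.eps * max(1, abs(rb[i])))
    return(f_range[1])          # flat spectrum: degenerate tie-break
  lo <- lf[max(1L, i - 1L)]
  hi <- lf[min(length(lf), i + 1L)]
  if (lo == hi) return(exp(lo))
  opt <- stats::optimize(
    function(l) Re(cm_single_shell(cell, medium, exp(l))),
    interval = c(lo, hi), maximum = TRUE, tol = tol / 2)
  exp(opt$maximum)
}

#' Scalar DEP force prefactor
#'
#' `F_DEP = 2 pi eps_l (d_c/2)^3 Re(beta) grad|E|^2`; this returns the
#' scalar multiplying `grad|E|^2` (units F m).
#'
#' @param medium a [medium_properties()] object.
#' @param d_c cell diameter (m), `> 0`.
#' @param re_beta real part of the CM factor (dimensionless).
#' @return scalar prefactor (F m).
#' @export
dep_prefactor <- function(medium, d_c, re_beta) {
  if (!is.finite(d_c) || d_c <= 0) stop("d_c must be positive")
  2 * pi * medium$epsilon_l * (d_c / 2)^3 * re_beta
}
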