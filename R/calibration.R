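# Least-squares calibration of the cubic gap-profile constant.

#' Fit the gap-profile constant C by linear least squares
#'
#' The cubic gap profile ([gap_potential()]) is linear in its constant:
#' `phi_C(x) = base(x) + C shape(x)` with
#' `base = (Vrms/pi)(pi/2 - (pi/2) s^3)` and
#' `shape = (Vrms/pi)(s^3 - s)`, `s` the gap-normalised coordinate.  The
#' least-squares minimiser of `sum_i (phi_C(x_i) - phi_ref(x_i))^2` is
#' therefore closed-form:
#' `C_opt = sum shape (ref - base) / sum shape^2`.
#'
#' With the canonical reference — the conformal-map solution for an
#' isolated coplanar electrode gap, [gap_reference_halfspace()] — the fit
#' gives `C_opt = 0.754718`, independent of geometry and drive (both model
#' and reference scale linearly with `Vrms` and depend on `x` only through
#' `s`).  A device-specific reference (the gap trace of a converged
#' [solve_mixed_bvp()] solution) may be supplied instead; note that the
#' finite channel yields a different, geometry-dependent optimum.
#'
#' @param reference data frame with columns `x_star` and `phi` (V), sampled
#'   strictly inside the gap; at least 10 samples.
#' @param geometry a [device_geometry()].
#' @param drive a [drive_settings()].
#' @return An object of class `"gap_fit"`: list with `C_opt`, `residual`
#'   (sum of squared deviations, V^2), `n_samples` and
#'   `reference_descriptor`.
#' @examples
#' p <- device_preset("A")
#' ref <- gap_fit_reference(p$geometry, p$drive)
#' coef(fit_gap_constant(ref, p$geometry, p$drive))   # 0.754718
#' @export
fit_gap_constant <- function(reference, geometry, drive) {
  x <- reference$x_star
  phi <- reference$phi
  g <- geometry$g
  if (length(x) < 10L) stop("need at least 10 reference samples")
  if (any(x <= g) || any(x >= 1 - g))
    stop("reference samples must lie strictly inside the gap")
  V <- drive$Vrms
  s <- (x - 0.5) / (0.5 - g)
  base <- (V / pi) * (pi / 2 - (pi / 2) * s^3)
  shape <- (V / pi) * (s^3 - s)
  den <- sum(shape^2)
  if (den <= .Machine$double.eps * V^2 * length(x))
    stop("degenerate design: the C-dependence vanishes on these samples")
  C_opt <- sum(shape * (phi - base)) / den
  res <- sum((base + C_opt * shape - phi)^2)
  structure(
    list(C_opt = C_opt, residual = res, n_samples = length(x),
         reference_descriptor = attr(reference, "descriptor")),
    class = "gap_fit")
}

#' Canonical calibration reference profile
#'
#' Samples the half-space conformal-map gap potential
#' ([gap_reference_halfspace()]) at `n` equispaced points strictly inside
#' the gap, excluding a margin of one sample spacing at each electrode
#' edge.  Feeding this to [fit_gap_constant()] reproduces the calibrated
#' default constant of [gap_approximation()].
#'
#' @param geometry a [device_geometry()].
#' @param drive a [drive_settings()].
#' @param n number of samples (default 512).
#' @return data frame with columns `x_star`, `phi`.
#' @export
gap_fit_reference <- function(geometry, drive, n = 512L) {
  g <- geometry$g
  h <- (1 - 2 * g) / (n + 1)
  x <- seq(g + h, 1 - g - h, length.out = n)
  out <- data.frame(x_star = x,
                    phi = gap_reference_halfspace(x, geometry, drive))
  attr(out, "descriptor") <- "half-space conformal-map gap solution"
  out
}

#' Gap-trace reference from a finite-difference solution
#'
#' Extracts the electrode-plane gap trace of a (mixed-problem) FD solution
#' as a calibration reference: `n` equispaced points strictly inside the
#' gap, excluding one grid cell at each electrode edge, linearly
#' interpolated between nodes.
#'
#' @param fd an `"fd_solution"`.
#' @param n number of samples (default 512).
#' @return data frame with columns `x_star`, `phi`.
#' @export
gap_fit_reference_fd <- function(fd, n = 512L) {
  g <- fd$geometry$g
  hx <- fd$grid$hx
  x <- seq(g + hx, 1 - g - hx, length.out = n)
  out <- data.frame(
    x_star = x,
    phi = stats::approx(fd$xs, fd$u[, fd$grid$ny], xout = x)$y)
  attr(out, "descriptor") <- sprintf(
    "FD %s-BVP gap trace (%d x %d nodes)", fd$bc, fd$grid$nx, fd$grid$ny)
  out
}

#' @export
coef.gap_fit <- function(object, ...) c(C = object$C_opt)

#' @export
print.gap_fit <- function(x, ...) {
  cat(sprintf("Gap-constant fit: C_opt = %.6f (residual %.3e V^2, n = %d)\n",
              x$C_opt, x$residual, x$n_samples))
  if (!is.null(x$reference_descriptor))
    cat("  reference:", x$reference_descriptor, "\n")
  invisible(x)
}
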