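# Parametric study of electrode width and spacing.

#' Average DEP force magnitude on the electrode surface
#'
#' Mean of `|F_DEP|` over the powered-electrode segment `x* in [0, w/L]`
#' evaluated at `y* = 1 - offset` (mirror symmetry makes the grounded
#' finger equivalent).  The continuum force is singular at the electrode
#' edge, so a small fixed dimensionless offset below the plane is used;
#' `offset = 0` is rejected.
#'
#' @param geometry a [device_geometry()].
#' @param drive a [drive_settings()].
#' @param prefactor scalar from [dep_prefactor()] (F m).
#' @param gap a [gap_approximation()].
#' @param n_terms series length (default 2000; the surface average
#'   converges much faster in `n` than pointwise edge values).
#' @param offset dimensionless evaluation depth below the electrode plane
#'   (default 1e-3, i.e. 0.5 um for a 500 um channel).
#' @param n_points number of equispaced sample points on the segment
#'   (`>= 200`).
#' @return mean `|F_DEP|` (N).
#' @export
mean_surface_force <- function(geometry, drive, prefactor,
                               gap = gap_approximation(),
                               n_terms = 2000L, offset = 1e-3,
                               n_points = 256L) {
  if (!is.finite(offset) || offset <= 0)
    stop("offset must be positive (the edge force is singular at offset 0)")
  if (n_points < 200L) stop("use at least 200 sample points")
  sol <- fourier_solution(geometry, drive, gap, n_terms = n_terms)
  x <- seq(0, geometry$g, length.out = n_points)
  mean(dep_force(sol, prefactor, x, 1 - offset)$F)
}

#' Electrode width/spacing sweep of the surface-averaged DEP force
#'
#' Evaluates [mean_surface_force()] on a Cartesian grid of electrode full
#' widths `2w` and spacings `d`, with pitch `L = 2w + d` and fixed channel
#' height.  Geometrically invalid combinations are skipped with a warning
#' and recorded as `NA`.
#'
#' @param widths electrode full widths `2w` (m).
#' @param spacings electrode spacings `d` (m).
#' @param H channel height (m).
#' @param drive a [drive_settings()].
#' @param prefactor scalar from [dep_prefactor()].
#' @param gap a [gap_approximation()].
#' @param n_terms,offset,n_points see [mean_surface_force()].
#' @return An object of class `"dep_sweep"`: list with `widths`, `spacings`,
#'   `F_mean` (matrix `length(spacings)` x `length(widths)`, N) and
#'   `metadata`.
#' @examples
#' \donttest{
#' p <- device_preset("A")
#' sw <- sweep_electrode_geometry(
#'   widths = seq(20e-6, 60e-6, length.out = 5),
#'   spacings = seq(20e-6, 60e-6, length.out = 5),
#'   H = 500e-6, drive = p$drive, prefactor = p$prefactor, n_terms = 500)
#' sweep_sensitivity(sw)
#' }
#' @export
sweep_electrode_geometry <- function(widths, spacings, H, drive, prefactor,
                                     gap = gap_approximation(),
                                     n_terms = 2000L, offset = 1e-3,
                                     n_points = 256L) {
  if (any(widths <= 0) || any(spacings <= 0))
    stop("widths and spacings must be positive")
  Fm <- matrix(NA_real_, length(spacings), length(widths),
               dimnames = list(
                 d_um = format(spacings * 1e6),
                 w2_um = format(widths * 1e6)))
  for (i in seq_along(spacings)) {
    for (j in seq_along(widths)) {
      geo <- tryCatch(
        device_geometry(H = H, w = widths[j] / 2, d = spacings[i]),
        error = function(e) NULL)
      if (is.null(geo)) {
        warning(sprintf("skipping invalid geometry 2w = %g, d = %g",
                        widths[j], spacings[i]))
        next
      }
      Fm[i, j] <- mean_surface_force(geo, drive, prefactor, gap,
                                     n_terms = n_terms, offset = offset,
                                     n_points = n_points)
    }
  }
  structure(
    list(widths = widths, spacings = spacings, F_mean = Fm,
         metadata = list(H = H, Vrms = drive$Vrms, f = drive$f,
                         prefactor = prefactor, n_terms = n_terms,
                         offset = offset, n_points = n_points,
                         C = gap$C)),
    class = "dep_sweep")
}

#' Sensitivity of the surface-averaged force to spacing vs width
#'
#' Central differences of the sweep matrix along each axis; reports the
#' mean absolute sensitivity to the spacing `d` and to the width `2w`, and
#' their ratio.  A ratio above one reproduces the design finding that the
#' force responds more sensitively to the electrode spacing than to the
#' electrode width.
#'
#' @param sweep a `"dep_sweep"`.
#' @return list with `dF_dd_mean`, `dF_dw_mean` (N/m), `ratio` and
#'   `spacing_dominates` (logical).
#' @export
sweep_sensitivity <- function(sweep) {
  Fm <- sweep$F_mean
  d <- sweep$spacings
  w <- sweep$widths
  nd <- length(d); nw <- length(w)
  if (nd < 3L || nw < 3L) stop("need at least a 3 x 3 sweep")
  dFdd <- (Fm[3:nd, ] - Fm[1:(nd - 2), ]) /
    (d[3:nd] - d[1:(nd - 2)])
  dFdw <- t(t(Fm[, 3:nw] - Fm[, 1:(nw - 2)]) / (w[3:nw] - w[1:(nw - 2)]))
  dd <- mean(abs(dFdd), na.rm = TRUE)
  dw <- mean(abs(dFdw), na.rm = TRUE)
  list(dF_dd_mean = dd, dF_dw_mean = dw, ratio = dd / dw,
       spacing_dominates = dd > dw)
}

#' @export
print.dep_sweep <- function(x, ...) {
  cat(sprintf(
    "Electrode geometry sweep: %d widths x %d spacings (H = %g um)\n",
    length(x$widths), length(x$spacings), x$metadata$H * 1e6))
  cat(sprintf("  mean |F_DEP| range: %.3e .. %.3e N\n",
              min(x$F_mean, na.rm = TRUE), max(x$F_mean, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.dep_sweep <- function(x, theta = 35, phi = 25, ...) {
  graphics::persp(x = x$spacings * 1e6, y = x$widths * 1e6,
                  z = log10(x$F_mean),
                  xlab = "spacing d (um)", ylab = "width 2w (um)",
                  zlab = "log10 mean |F_DEP| (N)",
                  theta = theta, phi = phi, ticktype = "detailed", ...)
  invisible(x)
}
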