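# Fourier-cosine-series solution of the channel cross-section potential.
#
# The dimensionless Laplace problem  phi_x*x* + (L/H)^2 phi_y*y* = 0  on
# [0,1]^2 with Neumann side walls, phi = 0 at the lid (y* = 0) and the
# Dirichlet data of top_boundary_profile() at the electrode plane (y* = 1)
# separates into
#
#   phi(x*, y*) = a0 y* + 2 sum_n I_n cos(k_n x*) sinh(k_n (H/L) y*) /
#                                                 sinh(k_n (H/L)),
#   k_n = n pi,  a0 = Vrms / 2,  I_n = int_0^1 f(x*) cos(k_n x*) dx*.
#
# The stored coefficients are the "reduced" I_n (the raw projections of the
# boundary profile); the sinh normalisation is folded into the evaluation as
# the ratio sinh(k_n (H/L) y*)/sinh(k_n (H/L)) in exp-difference form, since
# sinh(k_n H/L) itself overflows for n >~ 45 at H/L = 5.

#' Closed-form Fourier coefficients of the boundary profile
#'
#' Exact piecewise integration of [top_boundary_profile()] against
#' `cos(n pi x*)`: electrode plateaus contribute `sin` terms, the cubic gap
#' profile contributes first and third moments of `sin` over the half-gap.
#' Even-order coefficients vanish identically by the antisymmetry
#' `f(x) + f(1-x) = Vrms`.
#'
#' @param n integer vector of harmonic orders (`>= 1`).
#' @param geometry a [device_geometry()].
#' @param drive a [drive_settings()].
#' @param gap a [gap_approximation()].
#' @return numeric vector of reduced coefficients
#'   `I_n = int_0^1 f cos(k_n x*) dx*` (V).
#' @export
fourier_coefficients_closed_form <- function(n, geometry, drive,
                                             gap = gap_approximation()) {
  stopifnot(all(n >= 1))
  g <- geometry$g
  m <- 0.5 - g
  V <- drive$Vrms
  C <- gap$C
  k <- n * pi
  # J1 = int_0^m u sin(ku) du,  J3 = int_0^m u^3 sin(ku) du
  J1 <- sin(k * m) / k^2 - m * cos(k * m) / k
  J3 <- -m^3 * cos(k * m) / k + 3 * m^2 * sin(k * m) / k^2 +
    6 * m * cos(k * m) / k^3 - 6 * sin(k * m) / k^4
  V * sin(k * g) / k + cos(k / 2) * V * sin(k * m) / k +
    sin(k / 2) * (2 * V / pi) * ((C / m) * J1 + ((pi / 2 - C) / m^3) * J3)
}

#' Quadrature Fourier coefficients of the boundary profile
#'
#' Independent numerical projection of the boundary data onto the cosine
#' eigenbasis with [stats::integrate()], split at the electrode edges.
#' Serves as the normative oracle for
#' [fourier_coefficients_closed_form()]; the two agree to better than 1e-9
#' relative for `n <= 200`.
#'
#' @inheritParams fourier_coefficients_closed_form
#' @param profile optional replacement boundary-profile function of `x_star`
#'   (used e.g. for the uniform-plate degenerate check).
#' @return numeric vector of reduced coefficients (V).
#' @export
fourier_coefficients_quadrature <- function(n, geometry, drive,
                                            gap = gap_approximation(),
                                            profile = NULL) {
  stopifnot(all(n >= 1))
  if (is.null(profile))
    profile <- function(x) top_boundary_profile(x, geometry, drive, gap)
  g <- geometry$g
  vapply(n, function(ni) {
    k <- ni * pi
    f <- function(x) profile(x) * cos(k * x)
    pieces <- c(0, g, 1 - g, 1)
    sum(vapply(seq_len(3), function(j) {
      r <- tryCatch(
        stats::integrate(f, pieces[j], pieces[j + 1], rel.tol = 1e-12,
                         abs.tol = 1e-13,
                         subdivisions = max(200L, 8L * ni)),
        error = function(e) stop("quadrature failure at n = ", ni, ": ",
                                 conditionMessage(e)))
      r$value
    }, numeric(1)))
  }, numeric(1))
}

#' Fourier-series solution of the channel potential
#'
#' Builds the truncated cosine-series solution for a device geometry, drive
#' and gap constant.  The returned object evaluates the potential, electric
#' field, `grad |E|^2` and DEP force anywhere in the cross-section via
#' [predict.fourier_solution()] or the dedicated accessors
#' ([potential()], [electric_field()], [grad_E_squared()], [dep_force()]).
#'
#' @param geometry a [device_geometry()].
#' @param drive a [drive_settings()].
#' @param gap a [gap_approximation()].
#' @param n_terms series truncation length (default 10000, which bounds the
#'   boundary-reconstruction error well below 0.1 % of `Vrms` away from the
#'   electrode edges).
#' @param method coefficient route: exact `"closed_form"` (default) or the
#'   `"quadrature"` oracle (slow for large `n_terms`).
#' @param profile optional replacement top-boundary profile function (passed
#'   to the quadrature route only; forces `method = "quadrature"`).
#' @return An object of class `"fourier_solution"`: a list with the inputs
#'   plus `a0 = Vrms/2` and the reduced coefficients `a` (see file header
#'   for the normalisation).
#' @examples
#' p <- device_preset("A")
#' sol <- fourier_solution(p$geometry, p$drive, n_terms = 500)
#' potential(sol, 0.5, 1)           # Vrms/2 by symmetry
#' @export
fourier_solution <- function(geometry, drive, gap = gap_approximation(),
                             n_terms = 10000L,
                             method = c("closed_form", "quadrature"),
                             profile = NULL) {
  method <- match.arg(method)
  n_terms <- as.integer(n_terms)
  if (n_terms < 1L) stop("n_terms must be >= 1")
  if (!is.null(profile)) method <- "quadrature"
  a <- switch(method,
    closed_form = fourier_coefficients_closed_form(
      seq_len(n_terms), geometry, drive, gap),
    quadrature = fourier_coefficients_quadrature(
      seq_len(n_terms), geometry, drive, gap, profile = profile))
  if (!all(is.finite(a))) stop("non-finite series coefficients")
  a0 <- if (is.null(profile)) drive$Vrms / 2 else
    stats::integrate(profile, 0, 1, rel.tol = 1e-12,
                     subdivisions = 500L)$value
  structure(
    list(geometry = geometry, drive = drive, gap = gap,
         n_terms = n_terms, a0 = a0, a = a, method = method),
    class = "fourier_solution")
}

#' @export
print.fourier_solution <- function(x, ...) {
  cat("Fourier-series channel potential\n")
  print(x$geometry)
  print(x$drive)
  cat(sprintf("  gap constant C = %g, n_terms = %d (%s coefficients)\n",
              x$gap$C, x$n_terms, x$method))
  invisible(x)
}

#' @export
coef.fourier_solution <- function(object, ...) {
  c(a0 = object$a0, stats::setNames(object$a, paste0("a", seq_along(object$a))))
}

# ---- series evaluation engine -----------------------------------------

# Stable sinh/cosh ratios: for a = k_n H/L, t = a y*,
#   R = sinh(t)/sinh(a) = exp(t - a) (1 - exp(-2t)) / (1 - exp(-2a))
#   Q = cosh(t)/sinh(a) = exp(t - a) (1 + exp(-2t)) / (1 - exp(-2a))
# Both are computed as P x N matrices for P points and N terms, chunked over
# terms to bound memory.

.series_eval <- function(sol, x_star, y_star,
                         need = c("phi"), chunk = 4000L) {
  if (length(y_star) == 1L) y_star <- rep(y_star, length(x_star))
  if (length(x_star) == 1L) x_star <- rep(x_star, length(y_star))
  if (length(x_star) != length(y_star))
    stop("x_star and y_star lengths differ")
  if (any(x_star < 0 | x_star > 1 | y_star < 0 | y_star > 1))
    stop("points must lie in the unit square [0,1] x [0,1]")
  P <- length(x_star)
  N <- sol$n_terms
  HL <- sol$geometry$HL
  L <- sol$geometry$L
  acc <- sapply(need, function(q) numeric(P), simplify = FALSE)
  for (lo in seq(1L, N, by = chunk)) {
    hi <- min(lo + chunk - 1L, N)
    idx <- lo:hi
    k <- idx * pi
    a <- k * HL
    In <- sol$a[idx]
    # P x nc matrices
    Ck <- cos(outer(x_star, k))
    Sk <- if (any(need %in% c("Ex", "dyEx"))) sin(outer(x_star, k)) else NULL
    t_a <- outer(y_star, a, function(y, a) exp(a * (y - 1)))
    e2t <- exp(-2 * outer(y_star, a))
    e2a <- matrix(rep(-expm1(-2 * a), each = P), nrow = P)  # 1 - exp(-2a)
    R <- t_a * (1 - e2t) / e2a
    if (any(need %in% c("Ey", "dyEx"))) Qm <- t_a * (1 + e2t) / e2a
    for (q in need) {
      acc[[q]] <- acc[[q]] + switch(q,
        phi  = 2 * as.vector((Ck * R) %*% In),
        Ex   = (2 / L) * as.vector((Sk * R) %*% (In * k)),
        Ey   = -(2 / L) * as.vector((Ck * Qm) %*% (In * k)),
        dxEx = (2 / L^2) * as.vector((Ck * R) %*% (In * k^2)),
        dyEx = (2 / L^2) * as.vector((Sk * Qm) %*% (In * k^2)),
        stop("unknown quantity ", q))
    }
    if (!any(is.finite(In)) || max(abs(In)) == 0) break
  }
  if ("phi" %in% need) acc$phi <- acc$phi + sol$a0 * y_star
  if ("Ey" %in% need) acc$Ey <- acc$Ey - sol$a0 / sol$geometry$H
  acc
}

#' Potential of the series solution
#'
#' @param sol a [fourier_solution()].
#' @param x_star,y_star dimensionless coordinates in `[0, 1]` (vectors are
#'   paired, or one may be scalar).
#' @return potential (V).  `phi(x*, 0) = 0` holds exactly.
#' @export
potential <- function(sol, x_star, y_star) {
  .series_eval(sol, x_star, y_star, "phi")$phi
}

#' Electric field of the series solution
#'
#' Term-wise analytic differentiation of the series: `E = -grad phi` in
#' physical coordinates (`d/dx = (1/L) d/dx*`, `d/dy = (1/H) d/dy*`).
#'
#' @inheritParams potential
#' @return A data frame with columns `Ex`, `Ey` (V/m) and the normalised
#'   components `Ex_star`, `Ey_star` (`E H / Vrms`).
#' @export
electric_field <- function(sol, x_star, y_star) {
  v <- .series_eval(sol, x_star, y_star, c("Ex", "Ey"))
  sc <- sol$geometry$H / sol$drive$Vrms
  data.frame(Ex = v$Ex, Ey = v$Ey,
             Ex_star = v$Ex * sc, Ey_star = v$Ey * sc)
}

#' Gradient of the squared field magnitude
#'
#' `grad |E|^2 = 2 (Ex dEx + Ey dEy)` per component, with all derivatives
#' taken term-wise analytically.  Only two independent derivative sums are
#' needed since the field is curl-free and divergence-free
#' (`dEy/dx = dEx/dy`, `dEy/dy = -dEx/dx`).
#'
#' @inheritParams potential
#' @return A data frame with columns `gx`, `gy` (V^2/m^3).
#' @export
grad_E_squared <- function(sol, x_star, y_star) {
  v <- .series_eval(sol, x_star, y_star, c("Ex", "Ey", "dxEx", "dyEx"))
  data.frame(gx = 2 * (v$Ex * v$dxEx + v$Ey * v$dyEx),
             gy = 2 * (v$Ex * v$dyEx - v$Ey * v$dxEx))
}

#' DEP force field of the series solution
#'
#' `F_DEP = prefactor * grad |E|^2` with the scalar from [dep_prefactor()].
#' The normalised magnitude uses the reference force scale
#' `F_R = prefactor Vrms^2 / H^3`.
#'
#' @inheritParams potential
#' @param prefactor scalar from [dep_prefactor()] (F m).
#' @return A data frame with columns `Fx`, `Fy` (N), `F` (magnitude, N) and
#'   `F_star` (`|F|/F_R`, dimensionless).
#' @export
dep_force <- function(sol, prefactor, x_star, y_star) {
  if (!is.finite(prefactor)) stop("prefactor must be finite")
  gr <- grad_E_squared(sol, x_star, y_star)
  Fx <- prefactor * gr$gx
  Fy <- prefactor * gr$gy
  Fr <- abs(prefactor) * sol$drive$Vrms^2 / sol$geometry$H^3
  Fm <- sqrt(Fx^2 + Fy^2)
  data.frame(Fx = Fx, Fy = Fy, F = Fm,
             F_star = if (Fr > 0) Fm / Fr else NA_real_)
}

#' @export
predict.fourier_solution <- function(object, x_star, y_star,
                                     what = c("phi", "field", "gradE2",
                                              "force"),
                                     prefactor = NULL, ...) {
  what <- match.arg(what)
  switch(what,
    phi = data.frame(x_star = x_star, y_star = y_star,
                     phi = potential(object, x_star, y_star)),
    field = cbind(data.frame(x_star = x_star, y_star = y_star),
                  electric_field(object, x_star, y_star)),
    gradE2 = cbind(data.frame(x_star = x_star, y_star = y_star),
                   grad_E_squared(object, x_star, y_star)),
    force = {
      if (is.null(prefactor)) stop("`prefactor` is required for the force")
      cbind(data.frame(x_star = x_star, y_star = y_star),
            dep_force(object, prefactor, x_star, y_star))
    })
}

# ---- lattice sampling --------------------------------------------------

#' Sample the series solution on a rectangular lattice
#'
#' Evaluates potential, field, `grad |E|^2` and DEP force on a uniform
#' `nx x ny` lattice of the dimensionless cross-section (boundary lines
#' included).  On the two Dirichlet boundary rows (`y* = 0` and `y* = 1`)
#' the derivative-based quantities (`grad |E|^2` and the force) are masked
#' with `NA`: the continuum values there are truncation-dependent at the
#' electrode edges.
#'
#' Uses the lattice separability of the series (one matrix product per
#' quantity) and is much faster than pointwise evaluation.
#'
#' @param sol a [fourier_solution()].
#' @param prefactor scalar from [dep_prefactor()], or `NULL` to skip forces.
#' @param nx,ny lattice size (`>= 2`).
#' @return A long-format data frame of class `"field_grid"` with columns
#'   `x_star`, `y_star`, `phi`, `phi_star`, `Ex`, `Ey`, `E_star`, `gx`,
#'   `gy`, `Fx`, `Fy`, `F_star`, plus attributes `nx`, `ny`, `geometry`,
#'   `drive`.
#' @export
field_grid <- function(sol, prefactor = NULL, nx = 101L, ny = 101L) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 2L || ny < 2L) stop("nx and ny must be >= 2")
  xs <- seq(0, 1, length.out = nx)
  ys <- seq(0, 1, length.out = ny)
  N <- sol$n_terms
  k <- seq_len(N) * pi
  a <- k * sol$geometry$HL
  In <- sol$a
  L <- sol$geometry$L
  H <- sol$geometry$H
  V <- sol$drive$Vrms
  Ck <- cos(outer(xs, k))          # nx x N
  Sk <- sin(outer(xs, k))
  ta <- outer(a, ys, function(a, y) exp(a * (y - 1)))   # N x ny
  e2t <- exp(-2 * outer(a, ys))
  den <- -expm1(-2 * a)
  Rm <- ta * (1 - e2t) / den
  Qm <- ta * (1 + e2t) / den
  phi <- matrix(sol$a0 * rep(ys, each = nx), nx, ny) +
    2 * (Ck %*% (In * Rm))
  Ex <- (2 / L) * (Sk %*% ((In * k) * Rm))
  Ey <- -sol$a0 / H - (2 / L) * (Ck %*% ((In * k) * Qm))
  dxEx <- (2 / L^2) * (Ck %*% ((In * k^2) * Rm))
  dyEx <- (2 / L^2) * (Sk %*% ((In * k^2) * Qm))
  gx <- 2 * (Ex * dxEx + Ey * dyEx)
  gy <- 2 * (Ex * dyEx - Ey * dxEx)
  gx[, c(1L, ny)] <- NA_real_      # derivative quantities masked on the
  gy[, c(1L, ny)] <- NA_real_      # Dirichlet boundary rows
  out <- data.frame(
    x_star = rep(xs, times = ny), y_star = rep(ys, each = nx),
    phi = as.vector(phi), phi_star = as.vector(phi) / V,
    Ex = as.vector(Ex), Ey = as.vector(Ey),
    E_star = sqrt(as.vector(Ex)^2 + as.vector(Ey)^2) * H / V,
    gx = as.vector(gx), gy = as.vector(gy))
  if (!is.null(prefactor)) {
    Fr <- abs(prefactor) * V^2 / H^3
    out$Fx <- prefactor * out$gx
    out$Fy <- prefactor * out$gy
    out$F_star <- sqrt(out$Fx^2 + out$Fy^2) / Fr
  }
  attr(out, "nx") <- nx
  attr(out, "ny") <- ny
  attr(out, "geometry") <- sol$geometry
  attr(out, "drive") <- sol$drive
  class(out) <- c("field_grid", "data.frame")
  out
}

#' @export
plot.fourier_solution <- function(x, what = c("phi", "F_star"),
                                  prefactor = NULL, nx = 101L, ny = 101L,
                                  ...) {
  what <- match.arg(what)
  fg <- field_grid(x, prefactor = prefactor, nx = nx, ny = ny)
  z <- switch(what, phi = fg$phi_star, F_star = log10(fg$F_star))
  graphics::image(
    x = seq(0, 1, length.out = nx), y = seq(0, 1, length.out = ny),
    z = matrix(z, nx, ny),
    xlab = "x*", ylab = "y*",
    main = switch(what, phi = "phi / Vrms", F_star = "log10 |F_DEP| / F_R"),
    col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(fg)
}
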