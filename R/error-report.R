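# Verification metrics: series solution vs finite-difference oracle.

#' Average relative errors along the electrode plane
#'
#' Compares the series solution with a finite-difference solution of the
#' true mixed problem along `y* = 1`: the normalised potential
#' `phi* = phi/Vrms` and field magnitude `E* = |E| H / Vrms` (series:
#' term-wise analytic; FD: one-sided/central second-order differences).
#'
#' Three averaging variants are computed (all in percent, electrode-edge
#' neighbourhoods excluded):
#' \describe{
#'   \item{`"segmented"` (default)}{integral (L1) relative error
#'     `sum|q_s - q_fd| / sum|q_fd|`, evaluated for each quantity over the
#'     segment where it is not imposed by the boundary conditions: the
#'     potential over the inter-electrode gap (on the electrodes it equals
#'     the Dirichlet data in both solutions), the field over the electrode
#'     segments (on the gap the true normal field is zero by the Neumann
#'     condition that the Dirichlet replacement gives up, so a gap
#'     comparison measures the discarded constraint rather than the field
#'     approximation).}
#'   \item{`"pointwise"`}{mean of `|q_s - q_fd| / max(|q_fd|, 0.001 scale)`
#'     over the whole line, `scale = 1` for the normalised quantities.}
#'   \item{`"scaled"`}{mean of `|q_s - q_fd|` over the whole line, in
#'     percent of the normalisation scale.}
#' }
#'
#' @param sol a [fourier_solution()].
#' @param fd an `"fd_solution"` from [solve_mixed_bvp()] on the same
#'   geometry and drive.
#' @param variant which variant to report as `delta_phi_star` /
#'   `delta_E_star`; all three are returned in `$all`.
#' @param edge_exclusion half-width (in `x*`) of the excluded neighbourhood
#'   of each electrode edge (default 0.01; the continuum field is singular
#'   at the edges).
#' @return An object of class `"error_report"`: list with
#'   `delta_phi_star`, `delta_E_star` (percent), `variant`,
#'   `edge_exclusion`, and the matrix `all` of every variant.
#' @export
error_report <- function(sol, fd,
                         variant = c("segmented", "pointwise", "scaled"),
                         edge_exclusion = 0.01) {
  variant <- match.arg(variant)
  if (!identical(fd$bc, "mixed"))
    warning("error_report() is normally used with the mixed-BVP oracle")
  if (abs(sol$geometry$g - fd$geometry$g) > 1e-12 ||
      abs(sol$geometry$HL - fd$geometry$HL) > 1e-12)
    stop("series and FD solutions use different geometries")
  xs <- fd$xs
  ny <- fd$grid$ny
  V <- sol$drive$Vrms
  g <- sol$geometry$g
  # series along y* = 1 (R = 1, Q = coth)
  k <- seq_len(sol$n_terms) * pi
  a <- k * sol$geometry$HL
  In <- sol$a
  coth <- 1 / tanh(pmin(a, 350)); coth[a > 350] <- 1
  Ck <- cos(outer(xs, k)); Sk <- sin(outer(xs, k))
  phi_s <- (sol$a0 + 2 * as.vector(Ck %*% In)) / V
  HLs <- sol$geometry$HL
  Ex_s <- (2 * HLs / V) * as.vector(Sk %*% (In * k))
  Ey_s <- -sol$a0 / V - (2 * HLs / V) * as.vector(Ck %*% (In * k * coth))
  E_s <- sqrt(Ex_s^2 + Ey_s^2)
  # FD along y* = 1
  ff <- field_from_grid(fd)
  phi_f <- fd$u[, ny] / V
  E_f <- ff$E_star[, ny]
  if (length(phi_s) == 0) stop("empty sample set")
  keep <- abs(xs - g) > edge_exclusion & abs(xs - (1 - g)) > edge_exclusion
  gapn <- keep & xs > g & xs < 1 - g
  eln <- keep & !(xs > g & xs < 1 - g)
  l1 <- function(s, fdv, sel) 100 * sum(abs(s - fdv)[sel]) / sum(abs(fdv[sel]))
  pw <- function(s, fdv, sel)
    100 * mean((abs(s - fdv) / pmax(abs(fdv), 1e-3))[sel])
  scm <- function(s, fdv, sel) 100 * mean(abs(s - fdv)[sel])
  all <- rbind(
    segmented = c(phi = l1(phi_s, phi_f, gapn), E = l1(E_s, E_f, eln)),
    pointwise = c(phi = pw(phi_s, phi_f, keep), E = pw(E_s, E_f, keep)),
    scaled = c(phi = scm(phi_s, phi_f, keep), E = scm(E_s, E_f, keep)))
  structure(
    list(delta_phi_star = all[variant, "phi"],
         delta_E_star = all[variant, "E"],
         variant = variant, edge_exclusion = edge_exclusion,
         all = all, n_samples = sum(keep)),
    class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf(
    "Series vs FD oracle along y* = 1 (%s variant, edges +/- %g excluded):\n",
    x$variant, x$edge_exclusion))
  cat(sprintf("  delta phi* = %.2f %%   delta E* = %.2f %%\n",
              x$delta_phi_star, x$delta_E_star))
  cat("  all variants (%):\n")
  print(round(x$all, 3))
  invisible(x)
}

#' Grid-convergence study of the finite-difference oracle
#'
#' Solves the mixed problem on a ladder of edge-aligned grids (each refining
#' the previous by an integer factor) and reports, for each successive
#' pair, the average relative difference of the field magnitude `|E|` at
#' the common interior nodes, excluding nodes within one coarse cell of the
#' two electrode-edge singular points.
#'
#' @param geometry a [device_geometry()].
#' @param drive a [drive_settings()].
#' @param grids list of [fd_grid()] objects, coarse to fine; each `nx - 1`
#'   must divide the next.
#' @param ... passed to [solve_mixed_bvp()].
#' @return numeric vector (percent), one entry per successive pair, with
#'   attribute `solutions` holding the `"fd_solution"` objects.
#' @export
grid_convergence <- function(geometry, drive, grids, ...) {
  if (length(grids) < 2L) stop("need at least two grids")
  sols <- lapply(grids, function(gr)
    solve_mixed_bvp(geometry, drive, gr, ...))
  out <- numeric(length(grids) - 1L)
  for (i in seq_len(length(grids) - 1L)) {
    out[i] <- field_difference(sols[[i]], sols[[i + 1L]])
  }
  attr(out, "solutions") <- sols
  out
}

#' Average relative field difference between two nested FD solutions
#'
#' Compares `|E|` of a coarse and a fine solution of the same problem at
#' the common interior nodes (the fine grid must refine the coarse one by
#' integer factors), excluding nodes within one coarse cell of the two
#' electrode-edge singular points.
#'
#' @param coarse,fine `"fd_solution"` objects on nested grids.
#' @return mean pointwise relative difference, in percent.
#' @export
field_difference <- function(coarse, fine) {
  geometry <- coarse$geometry
  rc <- (fine$grid$nx - 1L) / (coarse$grid$nx - 1L)
  ry <- (fine$grid$ny - 1L) / (coarse$grid$ny - 1L)
  if (abs(rc - round(rc)) > 1e-9 || abs(ry - round(ry)) > 1e-9)
    stop("grids are not nested (refinement ratio must be an integer)")
  rc <- as.integer(round(rc)); ry <- as.integer(round(ry))
  Ec <- field_from_grid(coarse)$E_star
  Ef <- field_from_grid(fine)$E_star
  ic <- seq_len(coarse$grid$nx)
  jc <- seq_len(coarse$grid$ny)
  Efc <- Ef[1L + rc * (ic - 1L), 1L + ry * (jc - 1L)]
  # interior common nodes only (boundary stencils differ between grids)
  ii <- 2:(coarse$grid$nx - 1L)
  jj <- 2:(coarse$grid$ny - 1L)
  xs <- coarse$xs[ii]; ys <- coarse$ys[jj]
  hx <- coarse$grid$hx; hy <- coarse$grid$hy
  g <- geometry$g
  near_edge <- outer(abs(xs - g) <= hx + 1e-12 |
                     abs(xs - (1 - g)) <= hx + 1e-12,
                     (1 - ys) <= hy + 1e-12, `&`)
  D <- abs(Ec[ii, jj] - Efc[ii, jj]) / pmax(abs(Efc[ii, jj]), 1e-12)
  100 * mean(D[!near_edge])
}
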