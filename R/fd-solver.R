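# Finite-difference oracle for the channel cross-section potential.
#
# Second-order 5-point discretisation of  phi_x*x* + (L/H)^2 phi_y*y* = 0
# on a uniform nx x ny node grid of the unit square.  Boundary conditions:
# Dirichlet 0 at the lid (y* = 0); homogeneous Neumann on the symmetry
# walls x* = 0, 1 (ghost-node reflection, second order); at the electrode
# plane (y* = 1) Dirichlet on the electrode segments and either the true
# homogeneous Neumann condition on the gap ("mixed" problem) or Dirichlet
# gap data ("dirichlet" problem).  Nodes where a Dirichlet segment meets
# the Neumann gap take the Dirichlet value.
#
# Solvers: geometric multigrid (V(2,2) cycles, red-black Gauss-Seidel
# smoothing, full-weighting restriction, bilinear prolongation, sparse
# Cholesky on the coarsest level) or a direct sparse Cholesky solve of the
# symmetrically scaled system (Matrix/CHOLMOD).  The grid chooser pairs
# ny - 1 ~ (H/L)(nx - 1) so the scaled problem is isotropic and point
# smoothing is effective.

#' Uniform finite-difference grid
#'
#' @param nx,ny node counts (`>= 3`).  The electrode edges `x* = w/L` and
#'   `1 - w/L` must coincide with grid nodes, i.e. `(nx - 1) w/L` must be
#'   an integer.
#' @param geometry a [device_geometry()] (used for the edge-alignment check
#'   and the anisotropy ratio).
#' @return An object of class `"fd_grid"` with fields `nx`, `ny`, `hx`,
#'   `hy`, `xs`, `ys`.
#' @export
fd_grid <- function(nx, ny, geometry) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 3L || ny < 3L) stop("nx and ny must be >= 3")
  al <- (nx - 1L) * geometry$g
  if (abs(al - round(al)) > 1e-9)
    stop("grid is not edge-aligned: (nx - 1) * w/L = ", al,
         " is not an integer")
  structure(
    list(nx = nx, ny = ny, hx = 1 / (nx - 1), hy = 1 / (ny - 1),
         xs = seq(0, 1, length.out = nx), ys = seq(0, 1, length.out = ny)),
    class = "fd_grid")
}

#' Edge-aligned grid near a target node count
#'
#' Chooses `nx` so that the electrode edges are node-aligned and
#' `(nx - 1)` is divisible by a high power of two (deep multigrid
#' hierarchy), with `ny - 1 = (H/L)(nx - 1)` rounded to the nearest
#' aligned value so the physical mesh is isotropic.
#'
#' @param geometry a [device_geometry()].
#' @param nodes approximate total node count.
#' @return An [fd_grid()].
#' @export
fd_grid_near <- function(geometry, nodes) {
  g <- geometry$g
  HL <- geometry$HL
  # smallest M with M * g integral (M <= 1000)
  M <- which(abs((1:1000) * g - round((1:1000) * g)) < 1e-9)[1]
  if (is.na(M)) stop("w/L is not a simple rational; choose the grid manually")
  base <- max(1L, as.integer(M))
  target_nx1 <- sqrt(nodes / HL)
  # multiples of base * 2^j closest to target, preferring deep hierarchies
  best <- NULL
  for (j in 6:0) {
    step <- base * 2^j
    nx1 <- step * max(1L, round(target_nx1 / step))
    if (abs(nx1 - target_nx1) / target_nx1 < 0.2 || j == 0) {
      best <- nx1
      break
    }
  }
  nx1 <- best
  ny1 <- max(2L, round(HL * nx1))
  fd_grid(nx1 + 1L, ny1 + 1L, geometry)
}

# ---- internal level machinery -----------------------------------------

.fd_level <- function(nx, ny, HL, g, top_bc, xs = seq(0, 1, length.out = nx)) {
  hx <- 1 / (nx - 1); hy <- 1 / (ny - 1)
  cx <- 1 / hx^2; cy <- (1 / HL)^2 / hy^2
  dir <- matrix(FALSE, nx, ny)
  dir[, 1] <- TRUE
  eps <- 1e-9
  if (top_bc == "dirichlet") dir[, ny] <- TRUE
  else dir[xs <= g + eps | xs >= 1 - g - eps, ny] <- TRUE
  ij <- outer(seq_len(nx), seq_len(ny), `+`)
  list(nx = nx, ny = ny, cx = cx, cy = cy, xs = xs, dir = dir,
       maskR = !dir & (ij %% 2 == 0), maskB = !dir & (ij %% 2 == 1))
}

.fd_pad <- function(u, nx, ny) {
  P <- matrix(0, nx + 2, ny + 2)
  P[2:(nx + 1), 2:(ny + 1)] <- u
  P[1, 2:(ny + 1)] <- u[2, ]          # Neumann reflection at x* = 0
  P[nx + 2, 2:(ny + 1)] <- u[nx - 1, ]
  P[2:(nx + 1), ny + 2] <- u[, ny - 1] # top reflection (gap nodes only)
  P
}

.fd_stencil <- function(u, lv) {
  P <- .fd_pad(u, lv$nx, lv$ny)
  lv$cx * (P[1:lv$nx, 2:(lv$ny + 1)] + P[3:(lv$nx + 2), 2:(lv$ny + 1)]) +
    lv$cy * (P[2:(lv$nx + 1), 1:lv$ny] + P[2:(lv$nx + 1), 3:(lv$ny + 2)])
}

.fd_smooth <- function(u, f, lv, sweeps = 2L) {
  d <- 2 * (lv$cx + lv$cy)
  for (s in seq_len(sweeps)) {
    un <- (.fd_stencil(u, lv) + f) / d
    u[lv$maskR] <- un[lv$maskR]
    un <- (.fd_stencil(u, lv) + f) / d
    u[lv$maskB] <- un[lv$maskB]
  }
  u
}

.fd_residual <- function(u, f, lv) {
  r <- f + .fd_stencil(u, lv) - 2 * (lv$cx + lv$cy) * u
  r[lv$dir] <- 0
  r
}

.fd_restrict <- function(r, lvf, lvc) {
  P <- .fd_pad(r, lvf$nx, lvf$ny)
  xi <- seq(1L, lvf$nx, by = 2L) + 1L
  yj <- seq(1L, lvf$ny, by = 2L) + 1L
  rc <- (4 * P[xi, yj] +
         2 * (P[xi - 1, yj] + P[xi + 1, yj] +
              P[xi, yj - 1] + P[xi, yj + 1]) +
         P[xi - 1, yj - 1] + P[xi + 1, yj - 1] +
         P[xi - 1, yj + 1] + P[xi + 1, yj + 1]) / 16
  rc[lvc$dir] <- 0
  rc
}

.fd_prolong <- function(ec, lvf) {
  ef <- matrix(0, lvf$nx, lvf$ny)
  io <- seq(1L, lvf$nx, by = 2L); jo <- seq(1L, lvf$ny, by = 2L)
  ef[io, jo] <- ec
  ie <- seq(2L, lvf$nx - 1L, by = 2L)
  je <- seq(2L, lvf$ny - 1L, by = 2L)
  ef[ie, jo] <- (ef[ie - 1L, jo] + ef[ie + 1L, jo]) / 2
  ef[, je] <- (ef[, je - 1L] + ef[, je + 1L]) / 2
  ef[lvf$dir] <- 0
  ef
}

# Symmetrically scaled sparse assembly over the non-Dirichlet nodes.
# Rows are scaled by rho = (1/2 at Neumann x-walls) * (1/2 at top gap row)
# which restores symmetry after ghost-node elimination; the result is an
# SPD M-matrix factorised by CHOLMOD.
.fd_assemble <- function(lv, f, dir_values) {
  nx <- lv$nx; ny <- lv$ny
  upd <- !lv$dir
  idx <- matrix(0L, nx, ny)
  idx[upd] <- seq_len(sum(upd))
  rho <- matrix(1, nx, ny)
  rho[1, ] <- rho[nx, ] <- 0.5
  topgap <- upd[, ny]
  rho[topgap, ny] <- rho[topgap, ny] * 0.5
  wE <- matrix(lv$cx, nx, ny); wE[1, ] <- 2 * lv$cx
  wW <- matrix(lv$cx, nx, ny); wW[nx, ] <- 2 * lv$cx
  wN <- matrix(lv$cy, nx, ny)
  wS <- matrix(lv$cy, nx, ny); wS[topgap, ny] <- 2 * lv$cy
  wE <- wE * rho; wW <- wW * rho; wN <- wN * rho; wS <- wS * rho
  n_un <- sum(upd)
  ti <- idx[upd]; tj <- idx[upd]
  tv <- (rho * 2 * (lv$cx + lv$cy))[upd]
  bvec <- (rho * f)[upd]
  couple <- function(di, dj, wmat) {
    iA <- max(1L, 1L - di):min(nx, nx - di)
    jA <- max(1L, 1L - dj):min(ny, ny - dj)
    iB <- iA + di; jB <- jA + dj
    srcU <- upd[iA, jA, drop = FALSE]
    dstU <- upd[iB, jB, drop = FALSE]
    W <- wmat[iA, jA, drop = FALSE]
    sel <- srcU & dstU
    ti <<- c(ti, idx[iA, jA, drop = FALSE][sel])
    tj <<- c(tj, idx[iB, jB, drop = FALSE][sel])
    tv <<- c(tv, -W[sel])
    sel2 <- srcU & !dstU
    if (any(sel2)) {
      tgt <- idx[iA, jA, drop = FALSE][sel2]
      add <- W[sel2] * dir_values[iB, jB, drop = FALSE][sel2]
      bb <- numeric(n_un); bb[tgt] <- add
      bvec <<- bvec + bb
    }
  }
  couple(1L, 0L, wE); couple(-1L, 0L, wW)
  couple(0L, 1L, wN); couple(0L, -1L, wS)
  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tv, dims = c(n_un, n_un))
  list(A = Matrix::forceSymmetric(A), b = bvec, idx = idx, upd = upd,
       rho = rho)
}

.fd_vcycle <- function(u, f, levels, l, coarse, nu = 2L) {
  lv <- levels[[l]]
  if (l == length(levels)) {
    fm <- (coarse$rho * f)[coarse$upd]
    x <- as.vector(Matrix::solve(coarse$fac, fm))
    u[coarse$upd] <- x
    return(u)
  }
  u <- .fd_smooth(u, f, lv, nu)
  rc <- .fd_restrict(.fd_residual(u, f, lv), lv, levels[[l + 1L]])
  ec <- .fd_vcycle(matrix(0, levels[[l + 1L]]$nx, levels[[l + 1L]]$ny),
                   rc, levels, l + 1L, coarse, nu)
  u <- u + .fd_prolong(ec, lv)
  .fd_smooth(u, f, lv, nu)
}

.fd_solve <- function(geometry, drive, grid, top_bc, top_values,
                      method = c("auto", "multigrid", "direct"),
                      tol = 1e-10, maxit = 60L, verbose = FALSE) {
  method <- match.arg(method)
  nx <- grid$nx; ny <- grid$ny
  HL <- geometry$HL; g <- geometry$g
  lv1 <- .fd_level(nx, ny, HL, g, top_bc, grid$xs)
  # Dirichlet value field
  dv <- matrix(0, nx, ny)
  dv[, ny] <- ifelse(lv1$dir[, ny], top_values, 0)
  if (method == "auto")
    method <- if (nx * ny <= 6e5) "direct" else "multigrid"
  if (method == "multigrid" &&
      ((nx - 1L) %% 2L != 0L || (ny - 1L) %% 2L != 0L))
    method <- "direct"
  # initial iterate: separable interpolation of the top data
  topv <- top_values
  gapsel <- !lv1$dir[, ny]
  if (top_bc == "mixed" && any(gapsel))
    topv[gapsel] <- drive$Vrms * (1 - g - grid$xs[gapsel]) / (1 - 2 * g)
  u <- outer(topv, grid$ys)
  u[, 1] <- 0
  u[lv1$dir] <- dv[lv1$dir]
  f <- matrix(0, nx, ny)
  if (method == "direct") {
    asm <- .fd_assemble(lv1, f, dv)
    fac <- Matrix::Cholesky(asm$A, LDL = FALSE)
    u[asm$upd] <- as.vector(Matrix::solve(fac, asm$b))
    relres <- 0
    r <- .fd_residual(u, f, lv1)
    relres <- sqrt(sum(r^2)) / max(sqrt(sum(dv^2)) * lv1$cy, 1e-300)
    iters <- 1L
  } else {
    levels <- list(lv1)
    repeat {
      lv <- levels[[length(levels)]]
      if ((lv$nx - 1L) %% 2L != 0L || (lv$ny - 1L) %% 2L != 0L ||
          lv$nx <= 32L || lv$ny <= 32L) break
      levels[[length(levels) + 1L]] <-
        .fd_level((lv$nx - 1L) / 2L + 1L, (lv$ny - 1L) / 2L + 1L,
                  HL, g, top_bc)
    }
    lvc <- levels[[length(levels)]]
    zc <- matrix(0, lvc$nx, lvc$ny)
    asm <- .fd_assemble(lvc, zc, zc)
    coarse <- list(fac = Matrix::Cholesky(asm$A, LDL = FALSE),
                   upd = asm$upd, rho = asm$rho)
    r0 <- sqrt(sum(.fd_residual(u, f, lv1)^2))
    if (r0 == 0) r0 <- 1
    relres <- 1
    iters <- 0L
    while (iters < maxit) {
      u <- .fd_vcycle(u, f, levels, 1L, coarse)
      iters <- iters + 1L
      relres <- sqrt(sum(.fd_residual(u, f, lv1)^2)) / r0
      if (verbose)
        message(sprintf("V-cycle %d: relative residual %.3e", iters, relres))
      if (relres < tol) break
    }
    if (relres >= tol)
      warning(sprintf(
        "multigrid stopped at relative residual %.3e after %d cycles",
        relres, iters))
  }
  structure(
    list(u = u, xs = grid$xs, ys = grid$ys, grid = grid,
         geometry = geometry, drive = drive, bc = top_bc,
         method = method, relres = relres, iterations = iters),
    class = "fd_solution")
}

#' Solve the true mixed boundary-value problem
#'
#' Finite-difference solution of the Laplace problem with the physical
#' boundary conditions: fixed potentials on the electrode segments of the
#' electrode plane, zero normal flux (Neumann) on the inter-electrode gap,
#' grounded lid, symmetry side walls.
#'
#' @param geometry a [device_geometry()].
#' @param drive a [drive_settings()].
#' @param grid an [fd_grid()] (see [fd_grid_near()]).
#' @param method `"auto"` (direct Cholesky up to ~6e5 nodes, multigrid
#'   above), `"multigrid"` or `"direct"`.
#' @param tol relative residual target for the multigrid iteration.
#' @param maxit maximum number of V-cycles.
#' @param verbose print per-cycle residuals.
#' @return An object of class `"fd_solution"` with the potential matrix `u`
#'   (`nx` x `ny`), node coordinates, solver diagnostics and `bc = "mixed"`.
#' @export
solve_mixed_bvp <- function(geometry, drive, grid,
                            method = c("auto", "multigrid", "direct"),
                            tol = 1e-10, maxit = 60L, verbose = FALSE) {
  top <- numeric(grid$nx)
  top[grid$xs <= geometry$g + 1e-9] <- drive$Vrms
  .fd_solve(geometry, drive, grid, "mixed", top, method, tol, maxit, verbose)
}

#' Solve the Dirichlet-replaced problem
#'
#' Same discretisation as [solve_mixed_bvp()] but with the gap Neumann
#' condition replaced by the Dirichlet data of [top_boundary_profile()]
#' (or a custom profile).  This is the same continuum problem the
#' Fourier series solves, so it differs from [fourier_solution()] only by
#' truncation and discretisation error.
#'
#' @inheritParams solve_mixed_bvp
#' @param gap a [gap_approximation()].
#' @param top_profile optional function of `x_star` replacing the whole
#'   top-boundary profile (e.g. a uniform plate for degenerate checks).
#' @return An `"fd_solution"` with `bc = "dirichlet"`.
#' @export
solve_dirichlet_bvp <- function(geometry, drive, gap = gap_approximation(),
                                grid,
                                method = c("auto", "multigrid", "direct"),
                                tol = 1e-10, maxit = 60L, verbose = FALSE,
                                top_profile = NULL) {
  top <- if (is.null(top_profile))
    top_boundary_profile(grid$xs, geometry, drive, gap)
  else top_profile(grid$xs)
  .fd_solve(geometry, drive, grid, "dirichlet", top, method, tol, maxit,
            verbose)
}

#' @export
print.fd_solution <- function(x, ...) {
  cat(sprintf(
    "FD %s-BVP solution: %d x %d nodes (%s), relative residual %.2e\n",
    x$bc, x$grid$nx, x$grid$ny, x$method, x$relres))
  invisible(x)
}

#' Electric field from a finite-difference potential
#'
#' Central differences at interior nodes, second-order one-sided stencils
#' on the boundary rows/columns, converted to physical units with the
#' `1/L`, `1/H` metric factors.
#'
#' @param fd an `"fd_solution"`.
#' @return A list with matrices `Ex`, `Ey` (V/m), `Ex_star`, `Ey_star`,
#'   `E_star` (normalised by `Vrms/H`).
#' @export
field_from_grid <- function(fd) {
  u <- fd$u
  nx <- fd$grid$nx; ny <- fd$grid$ny
  hx <- fd$grid$hx; hy <- fd$grid$hy
  dudx <- matrix(NA_real_, nx, ny)
  dudx[2:(nx - 1), ] <- (u[3:nx, ] - u[1:(nx - 2), ]) / (2 * hx)
  dudx[1, ] <- (-3 * u[1, ] + 4 * u[2, ] - u[3, ]) / (2 * hx)
  dudx[nx, ] <- (3 * u[nx, ] - 4 * u[nx - 1, ] + u[nx - 2, ]) / (2 * hx)
  dudy <- matrix(NA_real_, nx, ny)
  dudy[, 2:(ny - 1)] <- (u[, 3:ny] - u[, 1:(ny - 2)]) / (2 * hy)
  dudy[, 1] <- (-3 * u[, 1] + 4 * u[, 2] - u[, 3]) / (2 * hy)
  dudy[, ny] <- (3 * u[, ny] - 4 * u[, ny - 1] + u[, ny - 2]) / (2 * hy)
  Ex <- -dudx / fd$geometry$L
  Ey <- -dudy / fd$geometry$H
  sc <- fd$geometry$H / fd$drive$Vrms
  list(Ex = Ex, Ey = Ey,
       Ex_star = Ex * sc, Ey_star = Ey * sc,
       E_star = sqrt(Ex^2 + Ey^2) * sc)
}
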