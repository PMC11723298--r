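# Analytic series solution: boundary profile, coefficients, potential,
# field, grad|E|^2, DEP force, lattice sampling.

p <- type_a()
geoA <- p$geometry
drvA <- p$drive
V <- drvA$Vrms

test_that("gap profile: midpoint, antisymmetry, edge continuity", {
  expect_equal(gap_potential(0.5, geoA, drvA), V / 2)
  set.seed(1)
  x <- runif(20, 0.2501, 0.7499)
  expect_equal(gap_potential(x, geoA, drvA) +
               gap_potential(1 - x, geoA, drvA),
               rep(V, 20))
  # the cubic profile is continuous with the electrode potentials
  expect_equal(gap_potential(0.25 + 1e-10, geoA, drvA), V, tolerance = 1e-7)
  expect_equal(gap_potential(0.75 - 1e-10, geoA, drvA), 0, tolerance = 1e-7)
  expect_error(gap_potential(0.2, geoA, drvA), "gap")
  expect_error(gap_potential(0.25, geoA, drvA), "gap")
})

test_that("top boundary profile is the piecewise Dirichlet data", {
  expect_equal(top_boundary_profile(0, geoA, drvA), V)
  expect_equal(top_boundary_profile(1, geoA, drvA), 0)
  expect_equal(top_boundary_profile(0.1, geoA, drvA), V)
  # quadrature mean equals a0 = Vrms/2
  m <- integrate(function(x) top_boundary_profile(x, geoA, drvA),
                 0, 1, rel.tol = 1e-10, subdivisions = 500)$value
  expect_equal(m, V / 2, tolerance = 1e-9)
  expect_error(top_boundary_profile(1.5, geoA, drvA), "\\[0, 1\\]")
})

test_that("closed-form coefficients match the quadrature projection", {
  n <- 1:200
  cc <- fourier_coefficients_closed_form(n, geoA, drvA)
  cq <- fourier_coefficients_quadrature(n, geoA, drvA)
  odd <- n %% 2 == 1
  expect_equal(cc[odd], cq[odd], tolerance = 1e-9)
  # even coefficients vanish by antisymmetry of the boundary data
  expect_lt(max(abs(cc[!odd])), 1e-12 * max(abs(cc)))
  expect_lt(max(abs(cq[!odd])), 1e-9 * max(abs(cc)))
  # Riemann-Lebesgue decay
  expect_lt(abs(fourier_coefficients_closed_form(10001, geoA, drvA)),
            abs(cc[1]) * 1e-4)
  # a second geometry (Type B aspect ratios)
  pB <- device_preset("B")
  ccB <- fourier_coefficients_closed_form(n, pB$geometry, pB$drive)
  cqB <- fourier_coefficients_quadrature(n, pB$geometry, pB$drive)
  oddB <- abs(cqB) > 1e-12 * max(abs(cqB))
  expect_equal(ccB[oddB], cqB[oddB], tolerance = 1e-8)
})

sol <- fourier_solution(geoA, drvA, n_terms = 4000)

test_that("series solution satisfies the boundary and symmetry structure", {
  expect_equal(sol$a0, V / 2)
  expect_true(all(is.finite(sol$a)))
  # exact zero at the lid
  expect_identical(potential(sol, seq(0, 1, 0.05), 0),
                   rep(0, 21))
  # mirror identity phi(x,y) + phi(1-x,y) = Vrms y*
  set.seed(2)
  x <- runif(30); y <- runif(30)
  expect_equal(potential(sol, x, y) + potential(sol, 1 - x, y),
               V * y, tolerance = 1e-10)
  # interior value bounded by the drive
  expect_true(all(potential(sol, x, y) > -1e-6 &
                  potential(sol, x, y) < V + 1e-6))
})

test_that("boundary reconstruction at y*=1 converges to the profile", {
  big <- fourier_solution(geoA, drvA, n_terms = 10000)
  xs <- seq(0.0005, 0.9995, length.out = 1000)
  keep <- abs(xs - 0.25) > 0.005 & abs(xs - 0.75) > 0.005
  tp <- top_boundary_profile(xs, geoA, drvA)
  err <- abs(potential(big, xs, 1) - tp)
  expect_lt(mean(err[keep]) / V, 0.005)
  # mean-square error decreases with series length
  for (n in c(250, 1000, 4000)) {
    s <- fourier_solution(geoA, drvA, n_terms = n)
    assign(paste0("mse", n),
           mean((potential(s, xs, 1) - tp)^2))
  }
  expect_lt(mse1000, mse250)
  expect_lt(mse4000, mse1000)
})

test_that("electric field matches finite differences of the potential", {
  pts <- cbind(x = c(0.1, 0.3, 0.5, 0.62, 0.9),
               y = c(0.3, 0.9, 0.97, 0.5, 0.8))
  h <- 1e-6
  ef <- electric_field(sol, pts[, "x"], pts[, "y"])
  Ex_fd <- -(potential(sol, pts[, "x"] + h, pts[, "y"]) -
             potential(sol, pts[, "x"] - h, pts[, "y"])) /
    (2 * h * geoA$L)
  Ey_fd <- -(potential(sol, pts[, "x"], pts[, "y"] + h) -
             potential(sol, pts[, "x"], pts[, "y"] - h)) /
    (2 * h * geoA$H)
  expect_equal(ef$Ex, Ex_fd, tolerance = 1e-5)
  expect_equal(ef$Ey, Ey_fd, tolerance = 1e-5)
  # symmetry walls carry no tangential field
  expect_equal(electric_field(sol, c(0, 1), 0.5)$Ex, c(0, 0),
               tolerance = 1e-12 * V / geoA$L)
  # normalisation: E* Vrms/H recovers E
  expect_equal(ef$Ex_star * V / geoA$H, ef$Ex)
})

test_that("uniform-plate degenerate limit gives the capacitor field", {
  su <- fourier_solution(geoA, drvA, n_terms = 50,
                         profile = function(x) rep(V, length(x)))
  expect_lt(max(abs(su$a)), 1e-10 * V)
  x <- c(0.2, 0.5, 0.8); y <- c(0.3, 0.6, 0.9)
  expect_equal(potential(su, x, y), V * y, tolerance = 1e-9)
  ef <- electric_field(su, x, y)
  expect_equal(ef$Ey, rep(-V / geoA$H, 3), tolerance = 1e-9)
  expect_equal(ef$Ex, rep(0, 3), tolerance = 1e-9 * V / geoA$L)
})

test_that("grad|E|^2 matches finite differences of |E|^2", {
  pts <- cbind(x = c(0.3, 0.5, 0.7, 0.2), y = c(0.95, 0.9, 0.97, 0.99))
  h <- 1e-6
  gr <- grad_E_squared(sol, pts[, "x"], pts[, "y"])
  E2 <- function(x, y) {
    ef <- electric_field(sol, x, y)
    ef$Ex^2 + ef$Ey^2
  }
  gx_fd <- (E2(pts[, "x"] + h, pts[, "y"]) -
            E2(pts[, "x"] - h, pts[, "y"])) / (2 * h * geoA$L)
  gy_fd <- (E2(pts[, "x"], pts[, "y"] + h) -
            E2(pts[, "x"], pts[, "y"] - h)) / (2 * h * geoA$H)
  expect_equal(gr$gx, gx_fd, tolerance = 1e-4)
  expect_equal(gr$gy, gy_fd, tolerance = 1e-4)
})

test_that("field gradient concentrates at the electrode edge", {
  y <- 0.995
  edge <- grad_E_squared(sol, geoA$g, y)
  mid <- grad_E_squared(sol, 0.5, y)
  expect_gt(sqrt(edge$gx^2 + edge$gy^2) / sqrt(mid$gx^2 + mid$gy^2), 10)
})

test_that("interior Laplace residual of the series vanishes", {
  h <- 1e-4
  for (pt in list(c(0.3, 0.5), c(0.6, 0.9), c(0.5, 0.98))) {
    x <- pt[1]; y <- pt[2]
    pxx <- (potential(sol, x + h, y) + potential(sol, x - h, y) -
            2 * potential(sol, x, y)) / h^2
    pyy <- (potential(sol, x, y + h) + potential(sol, x, y - h) -
            2 * potential(sol, x, y)) / h^2
    res <- pxx + (1 / geoA$HL)^2 * pyy
    scale <- max(abs(pxx), abs(pyy) / geoA$HL^2, V)
    expect_lt(abs(res) / scale, 1e-4)
  }
})

test_that("DEP force: quadratic drive scaling and normalised invariance", {
  pref <- p$prefactor
  f1 <- dep_force(sol, pref, 0.4, 0.97)
  drv2 <- drive_settings(Vrms = 2 * V, f = drvA$f)
  sol2 <- fourier_solution(geoA, drv2, n_terms = 4000)
  f2 <- dep_force(sol2, pref, 0.4, 0.97)
  expect_equal(f2$F, 4 * f1$F, tolerance = 1e-10)
  expect_equal(f2$F_star, f1$F_star, tolerance = 1e-10)
})

test_that("normalised force is minimal near the gap midline and decays
           with height", {
  pref <- p$prefactor
  # along a line just below the electrode plane, inside the gap
  xs <- seq(0.3, 0.7, length.out = 81)
  Fs <- dep_force(sol, pref, xs, 1 - 5e-3)$F_star
  expect_equal(xs[which.min(Fs)], 0.5, tolerance = 0.02)
  # x-gradient of |E|^2 nearly cancels at the midline
  gx_mid <- abs(grad_E_squared(sol, 0.5, 1 - 5e-3)$gx)
  gx_max <- max(abs(grad_E_squared(sol, xs, 1 - 5e-3)$gx))
  expect_lt(gx_mid / gx_max, 0.02)
  # two-to-three order decay between the near-surface region and 30 um
  # below the plane (the edge force falls off roughly quadratically with
  # distance from the edge singularity)
  y1 <- 1 - 1e-6 / geoA$H
  y30 <- 1 - 30e-6 / geoA$H
  r <- dep_force(sol, pref, 0.25, y30)$F /
    dep_force(sol, pref, 0.25, y1)$F
  expect_lt(r, 1 / 100)
})

test_that("field_grid equals pointwise evaluation and masks boundaries", {
  fg <- field_grid(sol, prefactor = p$prefactor, nx = 21, ny = 11)
  expect_equal(nrow(fg), 21 * 11)
  # corners of a 2x2 grid
  fg2 <- field_grid(sol, nx = 2, ny = 2)
  expect_equal(fg2$phi[fg2$y_star == 0], c(0, 0))
  # pointwise consistency at interior rows
  sub <- fg[fg$y_star > 0 & fg$y_star < 1, ]
  expect_equal(sub$phi, potential(sol, sub$x_star, sub$y_star),
               tolerance = 1e-12)
  ef <- electric_field(sol, sub$x_star, sub$y_star)
  expect_equal(sub$Ex, ef$Ex, tolerance = 1e-12)
  gr <- grad_E_squared(sol, sub$x_star, sub$y_star)
  expect_equal(sub$gx, gr$gx, tolerance = 1e-12)
  # derivative quantities are masked on the Dirichlet rows
  expect_true(all(is.na(fg$gx[fg$y_star %in% c(0, 1)])))
  # mirror symmetry scan on the lattice
  fg3 <- field_grid(sol, nx = 201, ny = 41)
  m <- matrix(fg3$phi, 201, 41)
  ys <- seq(0, 1, length.out = 41)
  expect_equal(m + m[201:1, ],
               matrix(rep(V * ys, each = 201), 201, 41),
               tolerance = 1e-9)
})
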