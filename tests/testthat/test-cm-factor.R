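# Clausius-Mossotti machinery: complex permittivity, two-phase and
# single-shell factors, spectra, peak frequency, DEP prefactor.

test_that("complex permittivity follows the physics sign convention", {
  expect_equal(complex_permittivity(6.9e-10, 0, 1e6), 6.9e-10 + 0i)
  # high-frequency limit: imaginary part vanishes
  expect_equal(Im(complex_permittivity(6.9e-10, 1e-3, 1e15)), 0,
               tolerance = 1e-17)
  # direct arithmetic at the device operating point
  w <- 2 * pi * 8.5e6
  ep <- complex_permittivity(6.9e-10, 1e-3, w)
  expect_equal(Re(ep), 6.9e-10)
  expect_equal(Im(ep), -1e-3 / w)
  expect_error(complex_permittivity(1e-10, 1e-3, 0), "positive")
})

test_that("two-phase CM factor has the textbook limits", {
  em <- complex_permittivity(6.9e-10, 1e-3, 2 * pi * 1e6)
  expect_equal(cm_factor(em, em), 0 + 0i)
  # perfectly polarisable particle
  expect_equal(Re(cm_factor(1e20 + 0i, em)), 1, tolerance = 1e-12)
  # highly conducting homogeneous sphere at low frequency: Re -> 1;
  # oracle = direct evaluation of the formula on a frequency grid
  fs <- 10^seq(2, 4, length.out = 50)
  w <- 2 * pi * fs
  b <- cm_factor(complex_permittivity(6.9e-10, 1, w),
                 complex_permittivity(6.9e-10, 1e-4, w))
  direct <- (complex(real = 6.9e-10, imaginary = -1 / w) -
             complex(real = 6.9e-10, imaginary = -1e-4 / w)) /
            (complex(real = 6.9e-10, imaginary = -1 / w) +
             2 * complex(real = 6.9e-10, imaginary = -1e-4 / w))
  expect_equal(b, direct)
  expect_true(all(Re(b) > 0.99))
})

test_that("single-shell factor agrees with the shelled-sphere route", {
  cl <- synthetic_cell()
  md <- sugar_medium()
  fs <- 10^seq(3, 9, length.out = 200)
  expect_equal(cm_single_shell(cl, md, fs), beta_shell_oracle(cl, md, fs),
               tolerance = 1e-13)
  # single value at the operating frequency
  expect_equal(cm_single_shell(cl, md, 8.5e6),
               beta_shell_oracle(cl, md, 8.5e6), tolerance = 1e-14)
})

test_that("single-shell factor has physical limits and bounds", {
  cl <- synthetic_cell()
  md <- sugar_medium()
  # DC limit: insulating membrane screens the interior -> -1/2
  expect_equal(Re(cm_single_shell(cl, md, 1e-4)), -0.5, tolerance = 1e-6)
  # high-frequency limit: dielectric contrast of the shelled sphere
  # (membrane capacitance in series with the interior permittivity)
  cmR <- cl$c_m * cl$d_c / 2
  eps_inf <- cmR * cl$epsilon_c / (cmR + cl$epsilon_c)
  hf <- (eps_inf - md$epsilon_l) / (eps_inf + 2 * md$epsilon_l)
  expect_equal(Re(cm_single_shell(cl, md, 1e13)), hf, tolerance = 1e-4)
  # positive DEP window around the device operating point
  expect_gt(Re(cm_single_shell(cl, md, 8.5e6)), 0.9)
  # bound property over randomised physical parameter sets
  set.seed(42)
  for (i in 1:20) {
    cl2 <- cell_model(diameter = runif(1, 5e-6, 30e-6),
                      c_membrane = runif(1, 0.005, 0.02),
                      epsilon_r = runif(1, 20, 80),
                      sigma = runif(1, 0.1, 1.5))
    md2 <- medium_properties(epsilon_r = runif(1, 40, 80),
                             sigma = 10^runif(1, -4, 0))
    rb <- Re(cm_single_shell(cl2, md2, 10^seq(3, 9, length.out = 200)))
    expect_true(all(rb >= -0.5 - 1e-9 & rb <= 1 + 1e-9))
  }
})

test_that("spectra are consistent, bounded and continuous", {
  cl <- synthetic_cell()
  md <- sugar_medium()
  sp1 <- cm_spectrum(cl, md, frequencies = 8.5e6)
  expect_equal(nrow(sp1), 1L)
  expect_equal(sp1$re_beta, Re(cm_single_shell(cl, md, 8.5e6)))
  fs <- 10^seq(3, 9, length.out = 1000)
  sp <- cm_spectrum(cl, md, fs)
  expect_true(all(sp$re_beta >= -0.5 - 1e-9 & sp$re_beta <= 1 + 1e-9))
  expect_lt(max(abs(diff(sp$re_beta))), 0.05)
  # pointwise oracle on the log grid
  expect_equal(sp$re_beta, Re(beta_shell_oracle(cl, md, fs)),
               tolerance = 1e-12)
  expect_error(cm_spectrum(cl, md, c(2e6, 1e6)), "increasing")
})

test_that("peak frequency matches an exhaustive log-grid scan", {
  cl <- synthetic_cell()
  md <- sugar_medium()
  fpk <- cm_peak_frequency(cl, md, c(1e3, 1e9))
  fs <- 10^seq(3, 9, length.out = 1e6)
  fscan <- fs[which.max(Re(cm_single_shell(cl, md, fs)))]
  expect_equal(fpk, fscan, tolerance = 1e-3)
  # bracket-widening invariance for an interior maximum
  fpk2 <- cm_peak_frequency(cl, md, c(1e2, 1e10))
  expect_equal(fpk, fpk2, tolerance = 1e-3)
  expect_error(cm_peak_frequency(cl, md, c(1e6, 1e3)), "f_lo < f_hi")
})

test_that("DEP prefactor scales correctly", {
  md <- sugar_medium()
  expect_identical(dep_prefactor(md, 15e-6, 0), 0)
  # hand calculation from the device operating values
  expect_equal(dep_prefactor(md, 15e-6, 0.98),
               2 * pi * 6.9e-10 * (7.5e-6)^3 * 0.98)
  # cubic in diameter, linear in re_beta and epsilon_l (randomised)
  set.seed(7)
  for (i in 1:10) {
    d <- runif(1, 1e-6, 50e-6); rb <- runif(1, -0.5, 1)
    s <- runif(1, 0.5, 3)
    expect_equal(dep_prefactor(md, 2 * d, rb), 8 * dep_prefactor(md, d, rb))
    expect_equal(dep_prefactor(md, d, s * rb), s * dep_prefactor(md, d, rb))
    md2 <- medium_properties(epsilon = s * md$epsilon_l, sigma = md$sigma_l)
    expect_equal(dep_prefactor(md2, d, rb), s * dep_prefactor(md, d, rb))
  }
})
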