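# Shared fixtures: a synthetic MCF10A-like cell parameter set (the cell
# properties are plausible literature-scale values, not measured ones) and
# the Type A device.

synthetic_cell <- function() {
  cell_model(diameter = 15e-6, c_membrane = 0.01,
             epsilon_r = 50, sigma = 0.5)
}

sugar_medium <- function(sigma = 1e-3) {
  medium_properties(epsilon = 6.9e-10, sigma = sigma)
}

type_a <- function() device_preset("A")

# independent direct evaluation of the single-shell CM factor through the
# effective shelled-sphere permittivity (oracle route, coded separately
# from the package's time-constant form)
beta_shell_oracle <- function(cell, medium, f) {
  w <- 2 * pi * f
  eps_i <- complex(real = cell$epsilon_c, imaginary = -cell$sigma_c / w)
  eps_l <- complex(real = medium$epsilon_l, imaginary = -medium$sigma_l / w)
  cmR <- cell$c_m * cell$d_c / 2
  eps_cell <- cmR * eps_i / (cmR + eps_i)
  (eps_cell - eps_l) / (eps_cell + 2 * eps_l)
}
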