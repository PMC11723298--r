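Package: depfield
Title: Electric Field and Dielectrophoretic Force Modelling for
    Interdigitated-Electrode Cell-Separation Devices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analytic Fourier-series solution of the electrostatic potential,
    electric field and dielectrophoretic (DEP) force in a parallel-plate
    microfluidic channel whose floor carries interdigitated electrodes and
    whose lid is a planar counter-electrode.  The mixed Dirichlet/Neumann
    boundary-value problem on the electrode plane is made separable by a
    cubic Dirichlet approximation of the inter-electrode potential whose
    single constant is calibrated by linear least squares against the
    conformal-map solution for a coplanar electrode gap.  A finite-difference
    multigrid solver of the true mixed problem serves as the verification
    oracle.  Includes the single-shell Clausius-Mossotti model for the
    frequency-dependent cell polarisability, field/force evaluation on
    grids, an electrode width/spacing parametric study, and CSV/VTK export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
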