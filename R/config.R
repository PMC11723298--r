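# Configuration reader: micrometre/volt units at the boundary, SI inside.

#' Read a run configuration from JSON
#'
#' The configuration uses the units customary for these devices
#' (micrometres, volts, hertz) and is normalised to SI on load.  Blocks:
#' \describe{
#'   \item{`geometry`}{`height_um`, `half_width_um` (or `width_um` for the
#'     full width `2w`), and exactly one of `pitch_um` / `spacing_um`.}
#'   \item{`drive`}{exactly one of `Vrms` / `Vpp`, and `f_Hz`.}
#'   \item{`medium`}{optional: `epsilon_Fm` or `epsilon_r`, `sigma_Sm`.}
#'   \item{`cell`}{optional: either `re_beta` directly, or the single-shell
#'     parameters `diameter_um`, `c_membrane_Fm2`, `epsilon_Fm`/`epsilon_r`,
#'     `sigma_Sm`.}
#'   \item{`series`}{optional: `n_terms`, `C`.}
#'   \item{`sampling`}{optional: `nx`, `ny`.}
#' }
#' Alternatively `preset` ("A", "B" or "C") seeds every block from
#' [device_preset()], with any further keys overriding.
#'
#' @param path path to a JSON file.
#' @return list with `geometry`, `drive`, `medium`, `cell`, `re_beta`,
#'   `prefactor`, `gap`, `n_terms`, `sampling`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list()
  if (!is.null(cfg$preset)) out <- device_preset(cfg$preset)
  if (!is.null(cfg$geometry)) {
    gb <- cfg$geometry
    if (is.null(gb$height_um)) stop("geometry: `height_um` is required")
    w <- if (!is.null(gb$half_width_um)) gb$half_width_um * 1e-6
    else if (!is.null(gb$width_um)) gb$width_um * 1e-6 / 2
    else stop("geometry: give `half_width_um` or `width_um`")
    has_p <- !is.null(gb$pitch_um); has_s <- !is.null(gb$spacing_um)
    if (has_p && has_s) {
      if (abs(gb$pitch_um - 2 * w * 1e6 - gb$spacing_um) > 1e-9)
        stop("geometry: contradictory `pitch_um` and `spacing_um` ",
             "(pitch != width + spacing)")
      has_s <- FALSE
    }
    if (!has_p && !has_s)
      stop("geometry: give `pitch_um` or `spacing_um`")
    out$geometry <- device_geometry(
      H = gb$height_um * 1e-6, w = w,
      L = if (has_p) gb$pitch_um * 1e-6 else NULL,
      d = if (has_s) gb$spacing_um * 1e-6 else NULL)
  }
  if (!is.null(cfg$drive)) {
    db <- cfg$drive
    if (!is.null(db$Vrms) && !is.null(db$Vpp))
      stop("drive: give only one of `Vrms` and `Vpp`")
    out$drive <- drive_settings(Vrms = db$Vrms, Vpp = db$Vpp, f = db$f_Hz)
  }
  if (!is.null(cfg$medium)) {
    mb <- cfg$medium
    out$medium <- medium_properties(epsilon = mb$epsilon_Fm,
                                    sigma = mb$sigma_Sm,
                                    epsilon_r = mb$epsilon_r)
  }
  if (!is.null(cfg$cell)) {
    cb <- cfg$cell
    if (!is.null(cb$re_beta)) {
      out$re_beta <- cb$re_beta
      out$d_c <- if (!is.null(cb$diameter_um)) cb$diameter_um * 1e-6
      else out$d_c
    } else {
      out$cell <- cell_model(diameter = cb$diameter_um * 1e-6,
                             c_membrane = cb$c_membrane_Fm2,
                             epsilon = cb$epsilon_Fm, sigma = cb$sigma_Sm,
                             epsilon_r = cb$epsilon_r)
      out$d_c <- out$cell$d_c
    }
  }
  if (!is.null(cfg$series)) {
    if (!is.null(cfg$series$n_terms)) out$n_terms <- cfg$series$n_terms
    if (!is.null(cfg$series$C)) out$gap <- gap_approximation(cfg$series$C)
  }
  if (is.null(out$gap)) out$gap <- gap_approximation()
  if (is.null(out$n_terms)) out$n_terms <- 10000L
  if (!is.null(cfg$sampling)) out$sampling <- cfg$sampling
  if (is.null(out$geometry)) stop("config must define a geometry or preset")
  if (is.null(out$drive)) stop("config must define a drive or preset")
  if (!is.null(out$medium) && !is.null(out$re_beta) && !is.null(out$d_c))
    out$prefactor <- dep_prefactor(out$medium, out$d_c, out$re_beta)
  out
}
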