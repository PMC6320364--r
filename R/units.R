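#' Unit system for energies and forces
#'
#' All quantities in the package live in a reduced unit system: positions in
#' micrometres, times in seconds, forces in femtoNewtons and energies in units
#' of the thermal energy kBT. The single physical constant required is kBT
#' itself expressed in fN um (1 fN um = 1e-21 J); the default 4.11 fN um
#' corresponds to approximately 298 K. Conversions between energies (kBT) and
#' forces (fN) always go through this object.
#'
#' @param kBT thermal energy in fN um; must be positive.
#' @return an object of class `pt_units`.
#' @examples
#' u <- units()
#' u$kBT
#' @export
units <- function(kBT = 4.11) {
  if (!is.numeric(kBT) || length(kBT) != 1 || !is.finite(kBT) || kBT <= 0) {
    abort("`kBT` must be a single positive number (fN um).")
  }
  structure(list(kBT = kBT), class = "pt_units")
}

#' @export
print.pt_units <- function(x, ...) {
  cat("<pt_units> kBT =", x$kBT, "fN um\n")
  invisible(x)
}

#' Friction coefficient from the Einstein-Stokes relation
#'
#' gamma = kBT / D, in fN s / um.
#'
#' @param D diffusion coefficient in um^2/s.
#' @param units a [units()] object.
#' @return friction coefficient(s) in fN s/um.
#' @export
friction_from_D <- function(D, units = pathtimes::units()) {
  stopifnot(all(D > 0))
  units$kBT / D
}
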