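#' Diffusion profiles
#'
#' A diffusion profile D(x) in um^2/s, either constant or tabulated with
#' linear interpolation. Tabulated profiles forbid evaluation outside their
#' grid; D must be positive everywhere.
#'
#' @param D diffusion coefficient(s) in um^2/s.
#' @param x tabulation grid (um, strictly increasing).
#' @return an object of class `pt_diffusion`.
#' @name diffusion
NULL

#' @rdname diffusion
#' @export
diffusion_constant <- function(D) {
  if (!is.numeric(D) || length(D) != 1 || !is.finite(D) || D <= 0) {
    abort("`D` must be a single positive number (um^2/s).")
  }
  structure(list(variant = "constant", D = D), class = "pt_diffusion")
}

#' @rdname diffusion
#' @export
diffusion_tabulated <- function(x, D) {
  if (length(x) != length(D) || length(x) < 2) abort("need matching x/D vectors.")
  if (any(diff(x) <= 0)) abort("`x` must be strictly increasing.")
  if (any(D <= 0)) abort("D(x) must be positive everywhere.")
  structure(list(variant = "tabulated", x = as.double(x), D = as.double(D)),
            class = "pt_diffusion")
}

#' @export
print.pt_diffusion <- function(x, ...) {
  if (x$variant == "constant") {
    cat("<pt_diffusion> constant D =", x$D, "um^2/s\n")
  } else {
    cat("<pt_diffusion> tabulated on [", min(x$x), ",", max(x$x), "] um, D in [",
        min(x$D), ",", max(x$D), "] um^2/s\n")
  }
  invisible(x)
}

#' Evaluate a diffusion profile
#'
#' @param spec a `pt_diffusion`.
#' @param x positions (um).
#' @return D(x) in um^2/s.
#' @export
diffusion_eval <- function(spec, x) {
  stopifnot(inherits(spec, "pt_diffusion"))
  if (spec$variant == "constant") return(rep(spec$D, length(x)))
  if (any(x < min(spec$x) | x > max(spec$x))) {
    abort("position outside tabulated diffusion domain.")
  }
  approx(spec$x, spec$D, xout = x)$y
}

as_diffusion <- function(D) {
  if (inherits(D, "pt_diffusion")) return(D)
  if (is.numeric(D) && length(D) == 1) return(diffusion_constant(D))
  abort("`diffusion` must be a pt_diffusion or a single positive number.")
}

dif_cpp <- function(spec) {
  if (spec$variant == "constant") list(type = 0L, D = spec$D)
  else list(type = 1L, x = spec$x, D = spec$D)
}
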