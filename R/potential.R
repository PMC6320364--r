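#' Energy landscapes
#'
#' A potential specification describes a one-dimensional free-energy landscape
#' U(x), stored in units of kBT with positions in micrometres. Four variants
#' are supported:
#'
#' * `potential_quartic(a, b, c)`: U(x)/kBT = a/4 x^4 + b/2 x^2 + c x, the
#'   bistable asymmetric form (a in kBT/um^4, b in kBT/um^2, c in kBT/um);
#'   `a > 0` is required for confinement and `c` controls the asymmetry
#'   about x = 0.
#' * `potential_linear(f)`: a constant tilt exerting force `f` (fN), i.e.
#'   U(x) = -f x / kBT.
#' * `potential_traps(centers, depths, widths)`: a mixture of Gaussian wells,
#'   U(x)/kBT = -sum_k depth_k exp(-(x - center_k)^2 / (2 width_k^2)),
#'   emulating optical point/line trap landscapes.
#' * `potential_tabulated(x, U)`: natural cubic-spline interpolation of
#'   tabulated values (x um, U kBT); evaluation outside the grid is an error.
#' * `potential_flat()`: U = 0 (free diffusion).
#'
#' @param a,b,c quartic coefficients in kBT/um^4, kBT/um^2, kBT/um.
#' @param f constant force in fN.
#' @param centers,depths,widths Gaussian well parameters (um, kBT, um);
#'   widths must be positive.
#' @param x,U tabulation grid (strictly increasing, um) and energies (kBT).
#' @return an object of class `pt_potential`.
#' @name potentials
NULL

new_potential <- function(variant, params) {
  structure(list(variant = variant, params = params), class = "pt_potential")
}

#' @rdname potentials
#' @export
potential_quartic <- function(a, b, c) {
  if (!is.finite(a) || a <= 0) abort("quartic potential requires `a` > 0.")
  new_potential("quartic", list(a = a, b = b, c = c))
}

#' @rdname potentials
#' @export
potential_linear <- function(f) {
  stopifnot(is.numeric(f), length(f) == 1, is.finite(f))
  new_potential("linear", list(f = f))
}

#' @rdname potentials
#' @export
potential_flat <- function() new_potential("flat", list())

#' @rdname potentials
#' @export
potential_traps <- function(centers, depths, widths) {
  if (!(length(centers) == length(depths) && length(depths) == length(widths))) {
    abort("`centers`, `depths`, `widths` must have equal length.")
  }
  if (any(widths <= 0)) abort("trap widths must be positive.")
  new_potential("traps", list(centers = as.double(centers),
                              depths = as.double(depths),
                              widths = as.double(widths)))
}

#' @rdname potentials
#' @export
potential_tabulated <- function(x, U) {
  if (length(x) != length(U) || length(x) < 4) {
    abort("tabulated potential needs >= 4 matching (x, U) pairs.")
  }
  if (any(diff(x) <= 0)) abort("tabulation grid must be strictly increasing.")
  spl <- splinefun(x, U, method = "natural")
  new_potential("tabulated", list(x = as.double(x), U = as.double(U), spline = spl))
}

#' @export
print.pt_potential <- function(x, ...) {
  p <- x$params
  desc <- switch(x$variant,
    flat = "U = 0",
    quartic = sprintf("U/kBT = %.4g/4 x^4 + %.4g/2 x^2 + %.4g x", p$a, p$b, p$c),
    linear = sprintf("constant force %.4g fN", p$f),
    traps = sprintf("%d Gaussian well(s)", length(p$centers)),
    tabulated = sprintf("spline through %d points on [%.3g, %.3g] um",
                        length(p$x), min(p$x), max(p$x))
  )
  cat("<pt_potential:", x$variant, "> ", desc, "\n", sep = "")
  invisible(x)
}

#' Bistable quartic potential from barrier heights
#'
#' Parameterizes the asymmetric double well U(x)/kBT = a/4 x^4 + b/2 x^2 + cx
#' by the symmetric barrier height `dU1` (kBT), the well asymmetry `dU2`
#' (kBT), and the well separation `L` (um), via a = 64 dU1 / L^4,
#' b = -a L^2 / 4, c = 2 dU2 / L. For `dU2 = 0` the wells sit at x = +/- L/2,
#' each `dU1` below the barrier top at x = 0.
#'
#' @param dU1 barrier height in kBT (> 0).
#' @param dU2 well asymmetry in kBT.
#' @param L well separation in um (> 0).
#' @return a quartic `pt_potential`.
#' @examples
#' quartic_from_barrier(5, 2, 1) # a = 320, b = -80, c = 4
#' @export
quartic_from_barrier <- function(dU1, dU2, L) {
  if (!is.finite(dU1) || dU1 <= 0) abort("`dU1` must be positive (kBT).")
  if (!is.finite(L) || L <= 0) abort("`L` must be positive (um).")
  a <- 64 * dU1 / L^4
  potential_quartic(a = a, b = -a * L^2 / 4, c = 2 * dU2 / L)
}

#' Evaluate a potential (kBT) or its force (fN)
#'
#' `potential_eval()` returns U(x) in kBT; `force_eval()` returns the
#' deterministic force -dU/dx converted to fN through `units$kBT`.
#'
#' @param spec a `pt_potential`.
#' @param x positions in um (vectorized). Tabulated potentials error outside
#'   their grid.
#' @param units a [units()] object.
#' @return numeric vector, kBT for `potential_eval`, fN for `force_eval`.
#' @export
potential_eval <- function(spec, x, units = pathtimes::units()) {
  stopifnot(inherits(spec, "pt_potential"))
  p <- spec$params
  switch(spec$variant,
    flat = rep(0, length(x)),
    quartic = p$a / 4 * x^4 + p$b / 2 * x^2 + p$c * x,
    linear = -p$f * x / units$kBT,
    traps = {
      out <- rep(0, length(x))
      for (k in seq_along(p$centers)) {
        out <- out - p$depths[k] * exp(-(x - p$centers[k])^2 / (2 * p$widths[k]^2))
      }
      out
    },
    tabulated = {
      if (any(x < min(p$x) | x > max(p$x))) {
        abort("position outside tabulated potential domain.")
      }
      p$spline(x)
    }
  )
}

#' @rdname potential_eval
#' @export
force_eval <- function(spec, x, units = pathtimes::units()) {
  stopifnot(inherits(spec, "pt_potential"))
  p <- spec$params
  kBT <- units$kBT
  switch(spec$variant,
    flat = rep(0, length(x)),
    quartic = -(p$a * x^3 + p$b * x + p$c) * kBT,
    linear = rep(p$f, length(x)),
    traps = {
      du <- rep(0, length(x))
      for (k in seq_along(p$centers)) {
        z <- (x - p$centers[k]) / p$widths[k]
        du <- du + p$depths[k] * (x - p$centers[k]) / p$widths[k]^2 * exp(-0.5 * z^2)
      }
      -du * kBT
    },
    tabulated = {
      if (any(x < min(p$x) | x > max(p$x))) {
        abort("position outside tabulated potential domain.")
      }
      -p$spline(x, deriv = 1) * kBT
    }
  )
}

#' Reconstruct a potential by integrating a force profile
#'
#' Cumulative trapezoidal integration U(x) = -int f dx from the left end of
#' the grid, converted to kBT; U at the first grid point is 0 by convention.
#'
#' @param x_grid strictly increasing positions (um).
#' @param f forces at `x_grid` (fN), same length.
#' @param units a [units()] object.
#' @return a tibble with columns `x` (um) and `U` (kBT).
#' @export
potential_from_force <- function(x_grid, f, units = pathtimes::units()) {
  if (length(x_grid) != length(f)) abort("`x_grid` and `f` must have equal length.")
  if (any(diff(x_grid) <= 0)) abort("`x_grid` must be strictly increasing.")
  tibble(x = x_grid, U = -cumtrapz(x_grid, f) / units$kBT)
}

# C++ dispatch form of a potential (internal)
pot_cpp <- function(spec, units, domain = NULL) {
  code <- c(flat = 0L, quartic = 1L, linear = 2L, traps = 3L, tabulated = 4L)
  p <- spec$params
  out <- list(type = code[[spec$variant]], par = numeric(0), kBT = units$kBT)
  if (spec$variant == "quartic") out$par <- c(p$a, p$b, p$c)
  if (spec$variant == "linear") out$par <- p$f
  if (spec$variant == "traps") out$par <- as.double(rbind(p$centers, p$depths, p$widths))
  if (spec$variant == "tabulated") {
    xg <- seq(min(p$x), max(p$x), length.out = max(2001L, 4L * length(p$x)))
    out$tx <- xg
    out$tf <- force_eval(spec, xg, units)
  }
  out
}
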