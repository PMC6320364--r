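# Quadrature grid over an interval with the Boltzmann-type weights used by
# the first-passage formulas. Energies enter only through differences, so a
# common offset is subtracted before exponentiating.
theory_grid <- function(potential, diffusion, interval, units, n) {
  interval <- as_interval(interval)
  x <- seq(interval[1], interval[2], length.out = n)
  u <- potential_eval(potential, x, units)
  u <- u - max(u)
  D <- diffusion_eval(as_diffusion(diffusion), x)
  if (any(D <= 0)) abort("D(x) must be positive on the interval.")
  list(x = x, u = u, D = D, h = x[2] - x[1])
}

#' Mean first-passage-time profile with two absorbing boundaries
#'
#' Solves D(x) tau'' + (f(x)/gamma(x)) tau' = -1 with tau = 0 at both
#' interval ends, by quadrature with the integrating factor e^{-U/kBT}. For
#' a flat potential this reduces to the free-diffusion result
#' tau(x0 = centre) = L^2 / (8 D).
#'
#' @param potential a `pt_potential`.
#' @param diffusion a `pt_diffusion` or single D (um^2/s).
#' @param interval `c(x_left, x_right)` (um).
#' @param units a [units()] object.
#' @param n quadrature nodes.
#' @return a tibble with columns `x` (um) and `tau` (s).
#' @export
mfpt_profile <- function(potential, diffusion, interval,
                         units = pathtimes::units(), n = 2001) {
  g <- theory_grid(potential, diffusion, interval, units, n)
  A <- exp(g$u) / g$D          # e^{U/kBT} / D
  B <- exp(-g$u)               # e^{-U/kBT}
  G <- cumtrapz(g$x, B)
  C <- trapz(g$x, A * G) / trapz(g$x, A)
  tibble(x = g$x, tau = cumtrapz(g$x, A * (C - G)))
}

#' Interpolate a mean first-passage time at a start position
#'
#' @param profile result of [mfpt_profile()].
#' @param x0 start position(s) (um).
#' @return tau(x0) in seconds.
#' @export
mfpt_at <- function(profile, x0) approx(profile$x, profile$tau, xout = x0)$y

#' Splitting probabilities of exit through either boundary
#'
#' Probability to leave the interval through the right (or left) boundary
#' first, starting from `x0`:
#' P_right(x0) = int_{xL}^{x0} e^{U/kBT}/D dx / int_{xL}^{xR} e^{U/kBT}/D dx,
#' and P_left = 1 - P_right. The 1/D weight matters only for spatially
#' varying D; for a constant force f (positive rightward) the expression
#' reduces to the closed form P_right = (1 + exp(-f L / 2 kBT))^{-1} from a
#' centred start, so downhill exits are always the more likely ones.
#'
#' @inheritParams mfpt_profile
#' @param x0 start position, strictly inside the interval (um).
#' @return an object of class `pt_splitting`: list with `P_left`, `P_right`.
#' @export
splitting_probability <- function(potential, diffusion, x0, interval,
                                  units = pathtimes::units(), n = 4097) {
  interval <- as_interval(interval)
  if (x0 <= interval[1] || x0 >= interval[2]) {
    abort("`x0` must lie strictly inside `interval`.")
  }
  g <- theory_grid(potential, diffusion, interval, units, n)
  W <- cumtrapz(g$x, exp(g$u) / g$D)
  p_right <- approx(g$x, W, xout = x0)$y / W[length(W)]
  structure(list(P_left = 1 - p_right, P_right = p_right), class = "pt_splitting")
}

#' @export
print.pt_splitting <- function(x, ...) {
  cat(sprintf("<pt_splitting> P_left = %.4f, P_right = %.4f\n", x$P_left, x$P_right))
  invisible(x)
}

new_density <- function(t, density, mass, direction) {
  structure(tibble(t = t, density = density),
            class = c("pt_density", class(tibble())),
            mass = mass, direction = direction)
}

#' @export
print.pt_density <- function(x, ...) {
  cat(sprintf("<pt_density> %s path-time density, %d time points, mass %.5f\n",
              attr(x, "direction"), nrow(x), attr(x, "mass")))
  NextMethod()
}

#' First moment of a path-time density
#'
#' @param density a `pt_density`.
#' @return the mean path time (s) implied by the tabulated density.
#' @export
density_mean <- function(density) {
  trapz(density$t, density$t * density$density) / trapz(density$t, density$density)
}

# Crank-Nicolson evolution from a grid delta; returns boundary effluxes on a
# graded time grid (with t = 0 prepended) until the surviving mass falls
# below mass_tol.
fp_fluxes <- function(g, i0, mass_tol, dt0 = NULL, dt_max = NULL, grow = 1.03,
                      max_steps = 4e5, n_implicit = 10L) {
  Dmax <- max(g$D)
  L <- g$x[length(g$x)] - g$x[1]
  if (is.null(dt0)) dt0 <- 0.2 * g$h^2 / Dmax
  if (is.null(dt_max)) dt_max <- (L^2 / (8 * Dmax)) / 500
  res <- cpp_cn_fluxes(g$u, g$D, g$h, as.integer(i0), dt0, dt_max, grow,
                       mass_tol, max_steps, as.integer(n_implicit))
  if (res$mass[length(res$mass)] >= mass_tol) {
    warn("Fokker-Planck horizon cap reached before the target residual mass.")
  }
  list(t = c(0, res$t), jl = c(0, res$jl), jr = c(0, res$jr),
       mass = c(1, res$mass))
}

#' Exit-path-time densities from the Fokker-Planck equation
#'
#' Evolves rho(x, t | x0) under d rho/dt = -dj/dx, j = (f/gamma) rho -
#' D(x) d rho/dx, with both interval boundaries absorbing
#' (rho(x_left, t) = rho(x_right, t) = 0), from a sharp initial peak at the
#' grid node nearest `x0` (Crank-Nicolson, conservative finite volumes,
#' graded time steps). The boundary probability effluxes j, normalized by the
#' splitting probabilities, are the uphill/downhill exit-path-time densities
#' rho_tau(t) = j(boundary, t | x0) / P(boundary). The time horizon is
#' extended automatically until the surviving probability falls below
#' `mass_tol`.
#'
#' @inheritParams splitting_probability
#' @param n_grid spatial nodes (>= 64; boundaries coincide with the interval
#'   ends).
#' @param mass_tol residual-mass stopping threshold.
#' @return a list with elements `left` and `right` (each a `pt_density` whose
#'   `mass` attribute should be 1 up to solver tolerance) and `splitting`
#'   (a `pt_splitting`).
#' @export
exit_time_density <- function(potential, diffusion, x0, interval,
                              units = pathtimes::units(), n_grid = 513,
                              mass_tol = 1e-4) {
  interval <- as_interval(interval)
  if (n_grid < 64) abort("`n_grid` must be >= 64.")
  if (x0 <= interval[1] || x0 >= interval[2]) {
    abort("`x0` must lie strictly inside the interval (boundary starts belong to transition_time_density).")
  }
  g <- theory_grid(potential, diffusion, interval, units, n_grid)
  i0 <- round((x0 - interval[1]) / g$h)
  if (i0 < 1 || i0 > n_grid - 2) abort("`x0` too close to a boundary for this grid.")
  sp <- splitting_probability(potential, diffusion, g$x[i0 + 1], interval, units)
  fl <- fp_fluxes(g, i0, mass_tol * min(sp$P_left, sp$P_right))
  list(
    left = new_density(fl$t, fl$jl / sp$P_left,
                       mass = trapz(fl$t, fl$jl) / sp$P_left, direction = "to_left"),
    right = new_density(fl$t, fl$jr / sp$P_right,
                        mass = trapz(fl$t, fl$jr) / sp$P_right, direction = "to_right"),
    splitting = sp
  )
}

#' Transition-path-time density across an interval
#'
#' Density of direct boundary-to-boundary path times, obtained as the
#' epsilon-limit of the conditioned exit problem: the initial peak is placed
#' at x0(epsilon) = x_left + epsilon (direction L to R), the flux through the
#' far boundary is normalized by the splitting probability P(x0(epsilon)),
#' and the limit epsilon -> 0 is taken by Richardson extrapolation from
#' epsilon = 4h and 2h (h the grid spacing). For a flat potential the first
#' moment is L^2 / (6 D). The forward and backward densities coincide for any
#' static landscape.
#'
#' @inheritParams exit_time_density
#' @param direction `"L_to_R"` or `"R_to_L"`.
#' @param eps_tol maximum relative change of the first moment between the two
#'   epsilon levels before extrapolation; larger changes raise a
#'   numerical-convergence error.
#' @return a `pt_density` with mass within 1e-3 of 1.
#' @export
transition_time_density <- function(potential, diffusion, interval,
                                    direction = c("L_to_R", "R_to_L"),
                                    units = pathtimes::units(), n_grid = 513,
                                    mass_tol = 1e-4, eps_tol = 0.01) {
  direction <- match.arg(direction)
  interval <- as_interval(interval)
  g <- theory_grid(potential, diffusion, interval, units, n_grid)
  W <- cumtrapz(g$x, exp(g$u) / g$D)
  Wtot <- W[length(W)]

  one_eps <- function(k) { # k grid cells away from the launch boundary
    if (direction == "L_to_R") {
      i0 <- k
      P <- W[i0 + 1] / Wtot
    } else {
      i0 <- n_grid - 1 - k
      P <- 1 - W[i0 + 1] / Wtot
    }
    fl <- fp_fluxes(g, i0, mass_tol * P)
    j <- if (direction == "L_to_R") fl$jr else fl$jl
    list(t = fl$t, d = j / P)
  }

  d2 <- one_eps(2L)
  d4 <- one_eps(4L)
  d4i <- approx(d4$t, d4$d, xout = d2$t, rule = 2)$y
  m2 <- trapz(d2$t, d2$t * d2$d)
  m4 <- trapz(d2$t, d2$t * d4i)
  if (abs(m4 - m2) / m2 > eps_tol) {
    abort(sprintf(
      "epsilon-limit not converged: first moment changed by %.2f%% between eps = 4h and 2h.",
      100 * abs(m4 - m2) / m2))
  }
  dens <- pmax(2 * d2$d - d4i, 0) # Richardson extrapolation, clipped at 0
  new_density(d2$t, dens, mass = trapz(d2$t, dens), direction = direction)
}

#' Mean transition-path time from double quadrature
#'
#' Evaluates the closed double-integral expression for the mean direct
#' transition time across an interval,
#' <tau_tr> = int dx w_-(x) W(x) (W_tot - W(x)) / W_tot with
#' W(x) = int_{xL}^{x} e^{U/kBT}/D dx' and w_-(x) = e^{-U/kBT}, using
#' cumulative trapezoid prefix sums (O(n)). The result is direction
#' independent and invariant under U -> U + const; for U = 0 it reduces to
#' L^2 / (6 D).
#'
#' @inheritParams mfpt_profile
#' @return the mean transition-path time (s).
#' @export
mean_transition_time <- function(potential, diffusion, interval,
                                 units = pathtimes::units(), n = 4097) {
  g <- theory_grid(potential, diffusion, interval, units, n)
  W <- cumtrapz(g$x, exp(g$u) / g$D)
  Wtot <- W[length(W)]
  trapz(g$x, W * (Wtot - W) * exp(-g$u)) / Wtot
}
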