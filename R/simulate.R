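#' Simulation configuration
#'
#' @param t_max total simulated time (s).
#' @param dt integration time step (s); the default 1e-3 s is far below the
#'   fastest relaxation time at the parameter scales this package targets.
#' @param x0 initial position (um).
#' @param record_stride record every `record_stride`-th step (>= 1).
#' @param bounds optional reflecting channel ends `c(lo, hi)` (um).
#' @param seed optional integer seed; fixed seed plus identical configuration
#'   gives a bit-identical trajectory.
#' @return an object of class `pt_sim_config`.
#' @export
sim_config <- function(t_max, dt = 1e-3, x0 = 0, record_stride = 1L,
                       bounds = NULL, seed = NULL) {
  if (!is.finite(dt) || dt <= 0) abort("`dt` must be positive.")
  if (!is.finite(t_max) || t_max < dt) abort("`t_max` must be >= dt.")
  record_stride <- as.integer(record_stride)
  if (record_stride < 1) abort("`record_stride` must be >= 1.")
  if (!is.null(bounds)) {
    if (length(bounds) != 2 || bounds[1] >= bounds[2]) {
      abort("`bounds` must be c(lo, hi) with lo < hi.")
    }
  }
  structure(list(dt = dt, t_max = t_max, x0 = x0,
                 record_stride = record_stride, bounds = bounds, seed = seed),
            class = "pt_sim_config")
}

new_trajectory <- function(t, x, fext = NULL, dt, seed = NULL) {
  df <- if (is.null(fext)) tibble(t = t, x = x) else tibble(t = t, x = x, fext = fext)
  structure(df, class = c("pt_trajectory", class(df)), dt = dt, seed = seed)
}

#' Integrate the overdamped Langevin equation
#'
#' Euler-Maruyama integration of
#' gamma(x) xdot = f_ext(t) - dU/dx + sqrt(2 kBT gamma(x)) xi(t),
#' with gamma(x) = kBT / D(x) (Einstein-Stokes) and, for tabulated D(x), the
#' kinetic-convention drift correction + dD/dx so that the stationary law
#' matches the Fokker-Planck current j = (f/gamma) rho - D(x) d rho/dx used by
#' the theory module. Optional reflecting bounds emulate closed channel ends.
#'
#' @param potential a `pt_potential`.
#' @param diffusion a `pt_diffusion` or a single D value (um^2/s).
#' @param telegraph optional [telegraph_spec()]; when present the recorded
#'   trajectory carries the instantaneous external force in `fext`.
#' @param config a [sim_config()].
#' @param units a [units()] object.
#' @return a `pt_trajectory` tibble with columns `t` (s), `x` (um) and, under
#'   telegraph forcing, `fext` (fN).
#' @examples
#' pot <- quartic_from_barrier(2, 0, 1)
#' traj <- simulate_overdamped(pot, 0.15, config = sim_config(10, seed = 1))
#' @export
simulate_overdamped <- function(potential, diffusion, telegraph = NULL,
                                config, units = pathtimes::units()) {
  stopifnot(inherits(potential, "pt_potential"), inherits(config, "pt_sim_config"))
  diffusion <- as_diffusion(diffusion)
  if (!is.null(config$seed)) set.seed(config$seed)
  n_steps <- round(config$t_max / config$dt)
  res <- cpp_simulate(
    pot_cpp(potential, units), dif_cpp(diffusion), tele_cpp(telegraph),
    config$dt, n_steps, config$x0, config$record_stride,
    if (is.null(config$bounds)) numeric(0) else as.double(config$bounds),
    if (is.null(telegraph)) 0L else tele_init_level(telegraph)
  )
  t_rec <- seq(0, by = config$dt * config$record_stride, length.out = length(res$x))
  new_trajectory(t_rec, res$x,
                 fext = if (!is.null(telegraph)) res$fext else NULL,
                 dt = config$dt * config$record_stride, seed = config$seed)
}

#' Automated exit protocol
#'
#' Emulates the drag-and-drop experiment: every repeat initializes the
#' particle at `config$x0` strictly inside `interval`, integrates the static
#' landscape until the first boundary crossing (crossing time linearly
#' interpolated between the straddling samples) or until `config$t_max`
#' (censored), and records the exit side and the exit-path time.
#'
#' @inheritParams simulate_overdamped
#' @param interval `c(x_left, x_right)` with `x_left < x0 < x_right` (um).
#' @param n_repeats number of repeats (>= 1).
#' @return a tibble with columns `rep`, `side` (factor left/right/censored)
#'   and `tau` (s; NA when censored).
#' @export
run_exit_protocol <- function(potential, diffusion, interval, config,
                              n_repeats, units = pathtimes::units()) {
  stopifnot(inherits(potential, "pt_potential"), inherits(config, "pt_sim_config"))
  diffusion <- as_diffusion(diffusion)
  interval <- as_interval(interval)
  if (n_repeats < 1) abort("`n_repeats` must be >= 1.")
  if (config$x0 <= interval[1] || config$x0 >= interval[2]) {
    abort("`config$x0` must lie strictly inside `interval`.")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  res <- cpp_exit_protocol(
    pot_cpp(potential, units), dif_cpp(diffusion),
    interval[1], interval[2], config$x0, config$dt,
    round(config$t_max / config$dt), as.integer(n_repeats)
  )
  tibble(
    rep = seq_len(n_repeats),
    side = factor(c("left", "censored", "right")[res$side + 2L],
                  levels = c("left", "right", "censored")),
    tau = ifelse(res$side == 0L, NA_real_, res$tau)
  )
}

#' Synthetic DNA-hairpin preset
#'
#' Emulates a hairpin-like bistable extension coordinate under two-level
#' force feedback: a symmetric quartic double well in the extension
#' coordinate (barrier `barrier` kBT, well separation `extension_span` um)
#' plus a telegraph force switching between `force_levels[1]` (high) and
#' `force_levels[2]` (low). Unequal level magnitudes tilt the landscape
#' differently in the two phases, so each of the folded/unfolded states
#' splits into a doublet (F+, F-, U+, U-) in the extension x force plane.
#'
#' The default levels place the dynamics in the adiabatic driving regime that
#' produces the doublet cycle: both tilted landscapes stay bistable (all four
#' states metastable), the mean dwell per force level (2/alpha) exceeds the
#' intra-well relaxation time, and the barrier crossing under favourable tilt
#' is faster than a force dwell while the unfavourable crossing is much
#' slower, so unfolding locks to high-force phases and folding to low-force
#' phases. The nonzero level midpoint makes the effective landscape differ
#' between the two phases, which renders the corner-to-corner path times
#' direction dependent.
#'
#' @param force_levels two distinct force levels (fN), high first.
#' @param alpha telegraph decorrelation rate (1/s).
#' @param barrier barrier height of the extension landscape (kBT, > 0).
#' @param extension_span separation of the folded/unfolded minima (um).
#' @param D diffusion coefficient of the extension coordinate (um^2/s).
#' @param t_max,dt,seed forwarded to [sim_config()]; `record_stride` defaults
#'   to 5 (5 ms sampling at the default dt), ample for the slow doublet
#'   kinetics.
#' @param record_stride recording stride.
#' @return a list with elements `potential`, `telegraph`, `diffusion`,
#'   `config`, `x_threshold` and `level_threshold` (classification
#'   thresholds), class `pt_hairpin_preset`.
#' @export
hairpin_preset <- function(force_levels = c(30, -18), alpha = 0.5, barrier = 5,
                           extension_span = 1, D = 0.15, t_max = 5000,
                           dt = 1e-3, record_stride = 5L, seed = NULL) {
  if (length(force_levels) != 2 || force_levels[1] == force_levels[2]) {
    abort("`force_levels` must be two distinct forces (fN).")
  }
  if (barrier <= 0) abort("`barrier` must be > 0 (kBT).")
  f_hi <- max(force_levels); f_lo <- min(force_levels)
  tel <- telegraph_spec(f0 = (f_hi - f_lo) / 2, alpha = alpha,
                        offset = (f_hi + f_lo) / 2)
  structure(list(
    potential = quartic_from_barrier(barrier, 0, extension_span),
    telegraph = tel,
    diffusion = diffusion_constant(D),
    config = sim_config(t_max = t_max, dt = dt, x0 = -extension_span / 2,
                        record_stride = record_stride, seed = seed),
    x_threshold = 0,
    level_threshold = tel$offset
  ), class = "pt_hairpin_preset")
}
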