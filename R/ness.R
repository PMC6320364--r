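#' Occupancy in the position x total-force plane
#'
#' Normalized 2D histogram of a telegraph-driven trajectory over position and
#' total force f_total = f_ext - dU/dx. At equilibrium (no telegraph) the
#' force marginal collapses onto a curve and the position marginal is
#' Boltzmann; under slow telegraph driving in a bistable landscape the
#' occupancy splits into distinct lobes (two positions x two force levels).
#'
#' @param traj a `pt_trajectory` with an `fext` column (fN).
#' @param potential the `pt_potential` that generated the dynamics.
#' @param x_edges,f_edges bin edges covering the data (um, fN).
#' @param units a [units()] object.
#' @return an object of class `pt_occupancy`: tibble with `x_bin`, `f_bin`,
#'   `x_mid`, `f_mid`, `p` (sums to 1).
#' @export
occupancy_2d <- function(traj, potential, x_edges, f_edges,
                         units = pathtimes::units()) {
  if (!"fext" %in% names(traj)) abort("trajectory has no `fext` column.")
  f_tot <- traj$fext + force_eval(potential, traj$x, units) # fext - dU/dx
  xi <- cut(traj$x, x_edges, labels = FALSE, include.lowest = TRUE)
  fi <- cut(f_tot, f_edges, labels = FALSE, include.lowest = TRUE)
  keep <- !is.na(xi) & !is.na(fi)
  if (!all(keep)) warn(sprintf("%d samples outside the bin range dropped.", sum(!keep)))
  tab <- table(factor(xi[keep], levels = seq_len(length(x_edges) - 1)),
               factor(fi[keep], levels = seq_len(length(f_edges) - 1)))
  xm <- (x_edges[-1] + x_edges[-length(x_edges)]) / 2
  fm <- (f_edges[-1] + f_edges[-length(f_edges)]) / 2
  out <- tidyr::expand_grid(x_bin = seq_along(xm), f_bin = seq_along(fm)) |>
    dplyr::mutate(x_mid = xm[.data$x_bin], f_mid = fm[.data$f_bin],
                  p = as.vector(t(tab))[ (.data$x_bin - 1) * length(fm) + .data$f_bin ] /
                    sum(tab))
  structure(out, class = c("pt_occupancy", class(out)),
            x_edges = x_edges, f_edges = f_edges)
}

#' Coarse-grained probability currents and broken detailed balance
#'
#' Bins a (position, total force) trajectory on a coarse 2D grid, counts net
#' crossings per unit time between adjacent bins (the antisymmetric edge
#' currents J_ij = -J_ji), and summarizes them as plaquette circulations: for
#' each elementary 2x2 plaquette, the sum of the four oriented edge currents
#' (counterclockwise). The signed `circulation` (sum over plaquettes, which
#' telescopes to the loop current around the binned domain) is zero in
#' expectation under detailed balance and changes sign under time reversal;
#' its absolute value is the nonnegative circulation score. The standard
#' error comes from recomputing the circulation on contiguous trajectory
#' blocks.
#'
#' Moves that change both coordinates within one sampling step are rare for
#' adequate sampling rates and are ignored (counted in `n_diagonal`).
#'
#' @inheritParams occupancy_2d
#' @param n_blocks contiguous blocks for the circulation standard error.
#' @return an object of class `pt_current`: list with `edges` (tibble of net
#'   currents), `plaquettes` (tibble of circulations, events/s), signed
#'   `circulation`, `score` = |circulation|, `se`, `z`, `n_moves`,
#'   `n_diagonal`.
#' @export
coarse_current_2d <- function(traj, potential, x_edges, f_edges,
                              units = pathtimes::units(), n_blocks = 10) {
  if (!"fext" %in% names(traj)) abort("trajectory has no `fext` column.")
  f_tot <- traj$fext + force_eval(potential, traj$x, units)
  xi <- cut(traj$x, x_edges, labels = FALSE, include.lowest = TRUE)
  fi <- cut(f_tot, f_edges, labels = FALSE, include.lowest = TRUE)
  keep <- !is.na(xi) & !is.na(fi)
  xi <- xi[keep]; fi <- fi[keep]; tt <- traj$t[keep]
  nx <- length(x_edges) - 1; nf <- length(f_edges) - 1
  T_total <- tt[length(tt)] - tt[1]

  circ_of <- function(idx) {
    x1 <- xi[idx[-length(idx)]]; x2 <- xi[idx[-1]]
    f1 <- fi[idx[-length(idx)]]; f2 <- fi[idx[-1]]
    dxb <- x2 - x1; dfb <- f2 - f1
    horiz <- abs(dxb) == 1 & dfb == 0
    vert <- dxb == 0 & abs(dfb) == 1
    diag <- abs(dxb) >= 1 & abs(dfb) >= 1
    # net counts on horizontal edges (x_bin i -> i+1 at force row j) and
    # vertical edges (f_bin j -> j+1 at position column i)
    Hx <- matrix(0, nx - 1, nf); Vf <- matrix(0, nx, nf - 1)
    if (any(horiz)) {
      i_edge <- pmin(x1[horiz], x2[horiz]); j_row <- f1[horiz]
      s <- sign(dxb[horiz])
      for (k in seq_along(i_edge)) Hx[i_edge[k], j_row[k]] <- Hx[i_edge[k], j_row[k]] + s[k]
    }
    if (any(vert)) {
      j_edge <- pmin(f1[vert], f2[vert]); i_col <- x1[vert]
      s <- sign(dfb[vert])
      for (k in seq_along(j_edge)) Vf[i_col[k], j_edge[k]] <- Vf[i_col[k], j_edge[k]] + s[k]
    }
    # counterclockwise plaquette circulation at (i, j):
    # bottom rightward + right upward - top rightward - left upward
    omega <- matrix(0, max(nx - 1, 1), max(nf - 1, 1))
    for (i in seq_len(nx - 1)) for (j in seq_len(nf - 1)) {
      omega[i, j] <- Hx[i, j] + Vf[i + 1, j] - Hx[i, j + 1] - Vf[i, j]
    }
    list(H = Hx, V = Vf, omega = omega, n_diag = sum(diag),
         n_moves = sum(horiz) + sum(vert))
  }

  full <- circ_of(seq_along(xi))
  circulation <- sum(full$omega) / T_total

  blocks <- split(seq_along(xi), cut(seq_along(xi), n_blocks, labels = FALSE))
  bc <- vapply(blocks, function(idx) {
    if (length(idx) < 2) return(NA_real_)
    sum(circ_of(idx)$omega) / (tt[idx[length(idx)]] - tt[idx[1]])
  }, numeric(1))
  bc <- bc[is.finite(bc)]
  se <- if (length(bc) >= 3) sd(bc) / sqrt(length(bc)) else NA_real_

  edges <- dplyr::bind_rows(
    tidyr::expand_grid(i = seq_len(max(nx - 1, 0)), j = seq_len(nf)) |>
      dplyr::mutate(type = "x", J = as.vector(full$H)[(.data$j - 1) * (nx - 1) + .data$i] / T_total),
    tidyr::expand_grid(i = seq_len(nx), j = seq_len(max(nf - 1, 0))) |>
      dplyr::mutate(type = "f", J = as.vector(full$V)[(.data$j - 1) * nx + .data$i] / T_total)
  )
  plaq <- tidyr::expand_grid(i = seq_len(max(nx - 1, 1)), j = seq_len(max(nf - 1, 1))) |>
    dplyr::mutate(omega = as.vector(full$omega)[(.data$j - 1) * max(nx - 1, 1) + .data$i] / T_total)

  structure(list(
    edges = edges, plaquettes = plaq,
    circulation = circulation, score = abs(circulation),
    se = se, z = circulation / se,
    n_moves = full$n_moves, n_diagonal = full$n_diag
  ), class = "pt_current")
}

#' @export
print.pt_current <- function(x, ...) {
  cat(sprintf(
    "<pt_current> circulation %.4g /s (score %.4g, se %.3g, z = %.2f), %d moves (%d diagonal)\n",
    x$circulation, x$score, x$se, x$z, x$n_moves, x$n_diagonal))
  invisible(x)
}

#' Time-reverse a trajectory
#'
#' Reverses the sample order while keeping the time axis increasing. Used as
#' the assumption-free null for current diagnostics: under detailed balance
#' the reversed trajectory is statistically equivalent, and the signed
#' circulation of the reversed trajectory is exactly minus the forward one.
#'
#' @param traj a trajectory data frame.
#' @return the reversed trajectory.
#' @export
time_reverse <- function(traj) {
  out <- traj[rev(seq_len(nrow(traj))), ]
  out$t <- traj$t[1] + (traj$t[nrow(traj)] - rev(traj$t))
  class(out) <- class(traj)
  out
}

#' Transition-path-time asymmetry versus telegraph decorrelation rate
#'
#' For each decorrelation rate alpha, simulates the driven landscape until at
#' least `min_events` direct transitions have been collected in each
#' direction, and reports directional means, SEMs, event counts, the mean
#' asymmetry and the KS p-value comparing the two directional path-time
#' distributions. Simulation proceeds in resumable chunks of one continuous
#' realization per alpha.
#'
#' @param alphas telegraph decorrelation rates (1/s).
#' @param setup list with elements `potential`, `diffusion`, `f0` (fN),
#'   `interval`; optional `offset` (fN), `dt` (s, default 1e-3), `x0` (um,
#'   default left well), `bounds`, `units`.
#' @param min_events minimum transitions per direction and alpha.
#' @param seed integer seed (one independent child stream per alpha).
#' @param max_time simulation-time cap per alpha (s), a safety stop.
#' @return an object of class `pt_sweep`: tibble with one row per alpha.
#' @export
asymmetry_sweep <- function(alphas, setup, min_events = 1000, seed = 1,
                            max_time = 2e5) {
  stopifnot(all(alphas > 0), min_events > 0)
  units <- setup$units %||% pathtimes::units()
  dt <- setup$dt %||% 1e-3
  interval <- as_interval(setup$interval)
  x0 <- setup$x0 %||% interval[1]
  bounds <- if (is.null(setup$bounds)) numeric(0) else as.double(setup$bounds)
  pot <- pot_cpp(setup$potential, units)
  dif <- dif_cpp(as_diffusion(setup$diffusion))

  out <- purrr::imap_dfr(as.double(alphas), function(alpha, k) {
    tel <- list(f0 = setup$f0, alpha = alpha, offset = setup$offset %||% 0)
    set.seed(child_seed(seed, k))
    ev <- collect_transitions(pot, dif, tel, interval, x0, dt, min_events,
                              max_time, bounds)
    lr <- ev$tau[ev$direction == "L_to_R"]
    rl <- ev$tau[ev$direction == "R_to_L"]
    ks <- if (length(lr) >= 5 && length(rl) >= 5) {
      ks_two_sample(lr, rl)$p_value
    } else NA_real_
    tibble(
      alpha = alpha,
      n_lr = length(lr), n_rl = length(rl),
      mean_lr = mean(lr), sem_lr = sd(lr) / sqrt(length(lr)),
      mean_rl = mean(rl), sem_rl = sd(rl) / sqrt(length(rl)),
      asymmetry = mean(lr) - mean(rl),
      ks_p = ks
    )
  })
  structure(out, class = c("pt_sweep", class(out)))
}

#' Collect direct transition events from one continuous run
#'
#' Simulates a single continuous realization (optionally telegraph-driven,
#' optionally confined by reflecting bounds) and streams interval-boundary
#' crossings, pairing them into direct transition events, until at least
#' `min_events` transitions were recorded in each direction or `max_time` of
#' simulated time has elapsed. Memory stays flat: only crossing events are
#' kept, not the trajectory.
#'
#' @inheritParams simulate_overdamped
#' @param interval transition interval `c(x_left, x_right)` (um).
#' @param min_events minimum events per direction.
#' @param dt integration step (s).
#' @param x0 start position (um).
#' @param bounds optional reflecting bounds (um).
#' @param seed integer seed.
#' @param max_time simulated-time cap (s).
#' @return a tibble of transition events (`direction`, `t_start`, `tau`).
#' @export
run_transition_protocol <- function(potential, diffusion, interval,
                                    telegraph = NULL, min_events = 500,
                                    dt = 1e-3, x0 = NULL, bounds = NULL,
                                    seed = NULL, max_time = 2e5,
                                    units = pathtimes::units()) {
  interval <- as_interval(interval)
  if (!is.null(seed)) set.seed(seed)
  collect_transitions(
    pot_cpp(potential, units), dif_cpp(as_diffusion(diffusion)),
    tele_cpp(telegraph), interval, x0 %||% mean(interval), dt, min_events,
    max_time, if (is.null(bounds)) numeric(0) else as.double(bounds))
}

# run one continuous driven realization in resumable chunks until enough
# transition events were observed in both directions (internal)
collect_transitions <- function(pot, dif, tel, interval, x0, dt, min_events,
                                max_time, bounds = numeric(0)) {
  chunk_steps <- 2e6
  state <- list(x = x0, lev = 0L, t = 0, t_next = -1)
  touches <- list()
  repeat {
    res <- cpp_touches(pot, dif, tel, interval[1], interval[2],
                       state$x, state$lev, state$t, state$t_next,
                       dt, chunk_steps, bounds)
    touches[[length(touches) + 1]] <-
      tibble(t = res$t, boundary = ifelse(res$boundary < 0, "L", "R"),
             dir = as.integer(res$dir))
    state <- list(x = res$x_final, lev = res$level_final,
                  t = res$t_final, t_next = res$t_next_final)
    ev <- pair_touches(dplyr::bind_rows(touches))
    n_lr <- sum(ev$direction == "L_to_R"); n_rl <- sum(ev$direction == "R_to_L")
    if ((n_lr >= min_events && n_rl >= min_events) || state$t >= max_time) {
      if (state$t >= max_time && (n_lr < min_events || n_rl < min_events)) {
        warn(sprintf("time cap reached with %d / %d events.", n_lr, n_rl))
      }
      return(ev)
    }
  }
}

#' Classify hairpin doublet states
#'
#' Labels every trajectory sample by folding state (F for extension below
#' `x_threshold`, U above) and telegraph phase (+ for external force above
#' `level_threshold`, - below): F+, F-, U+, U-. Samples within `buffer` of
#' `x_threshold` are labelled `transit`.
#'
#' @param traj a trajectory with `fext`.
#' @param x_threshold folding threshold on the extension coordinate (um).
#' @param level_threshold force level separating + from - (fN); typically the
#'   midpoint of the two feedback levels.
#' @param buffer half-width of the transit zone around `x_threshold` (um).
#' @return a factor of per-sample labels with levels F-, F+, U-, U+, transit.
#' @export
classify_hairpin_states <- function(traj, x_threshold = 0, level_threshold = 0,
                                    buffer = 0.1) {
  if (!"fext" %in% names(traj)) abort("trajectory has no `fext` column.")
  fold <- ifelse(traj$x < x_threshold - buffer, "F",
                 ifelse(traj$x > x_threshold + buffer, "U", "transit"))
  phase <- ifelse(traj$fext > level_threshold, "+", "-")
  lab <- ifelse(fold == "transit", "transit", paste0(fold, phase))
  factor(lab, levels = c("F-", "F+", "U-", "U+", "transit"))
}

#' Corner-to-corner doublet transition times
#'
#' Measures path times between the two diagonal corner states of the
#' doublet system: each U+ -> F- sample spans from the last exit of the U+
#' region to the first subsequent entry into F- (and symmetrically), so
#' dwells in the intermediate states (U-, F+) along the way are included.
#'
#' @param states per-sample labels from [classify_hairpin_states()].
#' @param traj the matching trajectory.
#' @param min_visits minimum number of visits to each corner state.
#' @return a tibble with columns `direction` (`U+_to_F-` / `F-_to_U+`),
#'   `t_start`, `tau` (s).
#' @export
doublet_transition_times <- function(states, traj, min_visits = 20) {
  stopifnot(length(states) == nrow(traj))
  r <- rle(as.character(states))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  corner <- r$values %in% c("U+", "F-")
  if (sum(r$values[corner] == "U+") < min_visits ||
      sum(r$values[corner] == "F-") < min_visits) {
    abort(sprintf("need >= %d visits to each of U+ and F-.", min_visits))
  }
  lab <- r$values[corner]
  t_in <- traj$t[starts[corner]]
  t_out <- traj$t[ends[corner]]
  # successive visits to different corners delimit a corner-to-corner path
  n <- length(lab)
  from <- lab[-n]; to <- lab[-1]
  sel <- from != to
  tibble(
    direction = factor(ifelse(from[sel] == "U+", "U+_to_F-", "F-_to_U+"),
                       levels = c("U+_to_F-", "F-_to_U+")),
    t_start = t_out[-n][sel],
    tau = t_in[-1][sel] - t_out[-n][sel]
  )
}
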