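make_driven_traj <- function(t_max = 3000, f0 = 82, alpha = 0.5, seed = SEED) {
  pot <- quartic_from_barrier(5, 2, 1)
  tel <- telegraph_spec(f0, alpha)
  list(pot = pot,
       traj = simulate_overdamped(pot, 0.15, tel,
                                  sim_config(t_max, record_stride = 10,
                                             x0 = -0.5, seed = seed)))
}

test_that("occupancy histograms are normalized and split into four lobes when driven", {
  d <- make_driven_traj(t_max = 2000, seed = child_seed(SEED, 601))
  occ <- suppressWarnings(
    occupancy_2d(d$traj, d$pot, c(-2, 0, 2), c(-1500, 0, 1500)))
  expect_equal(sum(occ$p), 1, tolerance = 1e-9)
  expect_true(all(occ$p >= 0))
  # all four (position x force) lobes are clearly populated (the two
  # disfavoured ones only through post-switch relaxation at this driving)
  expect_true(all(occ$p > 0.01))
})

test_that("equilibrium occupancy collapses onto the Boltzmann marginal", {
  pot <- quartic_from_barrier(2, 1, 1)
  tel0 <- telegraph_spec(0, 0.5) # zero amplitude: equilibrium with fext = 0
  tr <- simulate_overdamped(pot, 0.15, tel0,
                            sim_config(20000, record_stride = 200,
                                       seed = child_seed(SEED, 602)))
  # force marginal is a deterministic function of x: one force bin suffices
  expect_gt(boltzmann_chisq(tr$x[tr$t > 10], pot), 0.01)
  occ <- suppressWarnings(
    occupancy_2d(tr, pot, c(-2, 0, 2), c(-1500, 0, 1500)))
  expect_equal(sum(occ$p), 1, tolerance = 1e-9)
})

test_that("coarse-grained currents are antisymmetric and vanish at equilibrium", {
  pot <- quartic_from_barrier(2, 1, 1)
  tel0 <- telegraph_spec(0, 0.5)
  tr <- simulate_overdamped(pot, 0.15, tel0,
                            sim_config(3000, record_stride = 10,
                                       seed = child_seed(SEED, 603)))
  cur <- coarse_current_2d(tr, pot, c(-2, 0, 2), c(-1500, 0, 1500))
  expect_lt(abs(cur$z), 3)
  expect_equal(cur$score, abs(cur$circulation))
})

test_that("telegraph driving breaks detailed balance in the position-force plane", {
  d <- make_driven_traj(t_max = 3000, seed = child_seed(SEED, 604))
  cur <- coarse_current_2d(d$traj, d$pot, c(-2, 0, 2), c(-1500, 0, 1500))
  expect_gt(abs(cur$z), 3)
  # the time-reversed trajectory carries exactly the opposite circulation
  rev <- coarse_current_2d(time_reverse(d$traj), d$pot,
                           c(-2, 0, 2), c(-1500, 0, 1500))
  expect_equal(rev$circulation, -cur$circulation, tolerance = 1e-9)
})

test_that("path-time asymmetry appears at slow switching and fades at fast switching", {
  pot <- quartic_from_barrier(5, 2, 1)
  setup <- list(potential = pot, diffusion = 0.15, f0 = 82,
                interval = c(-0.4, 0.4))
  sw <- asymmetry_sweep(c(0.5, 50), setup, min_events = 300,
                        seed = child_seed(SEED, 605))
  expect_true(all(sw$n_lr >= 300 & sw$n_rl >= 300))
  expect_lt(sw$ks_p[sw$alpha == 0.5], 0.05)
  expect_lt(abs(sw$asymmetry[sw$alpha == 50]),
            abs(sw$asymmetry[sw$alpha == 0.5]))
  # SEMs shrink roughly as 1/sqrt(events)
  sw2 <- asymmetry_sweep(0.5, setup, min_events = 1200,
                         seed = child_seed(SEED, 606))
  expect_lt(sw2$sem_lr, sw$sem_lr[1])
})

test_that("zero telegraph amplitude yields symmetric path times at every rate", {
  pot <- quartic_from_barrier(2, 1, 1)
  setup <- list(potential = pot, diffusion = 0.15, f0 = 0,
                interval = c(-0.4, 0.4))
  sw <- asymmetry_sweep(c(0.5, 5), setup, min_events = 300,
                        seed = child_seed(SEED, 607))
  expect_true(all(sw$ks_p > 0.05))
  pooled_se <- sqrt(sw$sem_lr^2 + sw$sem_rl^2)
  expect_true(all(abs(sw$asymmetry) < 3 * pooled_se))
})

test_that("hairpin state labels respect thresholds and symmetry operations", {
  tr <- tibble::tibble(t = (0:5) * 0.1,
                       x = c(-0.5, -0.5, 0.02, 0.5, 0.5, -0.5),
                       fext = c(15, -9, -9, -9, 15, 15))
  st <- classify_hairpin_states(tr, 0, 3, buffer = 0.1)
  expect_equal(as.character(st), c("F+", "F-", "transit", "U-", "U+", "F+"))
  # flipping the force sign swaps only the +/- phase labels
  tr2 <- tr
  tr2$fext <- -tr2$fext
  st2 <- classify_hairpin_states(tr2, 0, -3, buffer = 0.1)
  expect_equal(gsub("[+-]$", "", as.character(st)),
               gsub("[+-]$", "", as.character(st2)))
  # a constant force occupies only two labels
  tr3 <- tr
  tr3$fext <- 15
  expect_lte(length(unique(as.character(
    classify_hairpin_states(tr3, 0, 3, buffer = 0.1)))), 3)
})

test_that("driven hairpin doublet transitions are asymmetric; degenerate preset is not", {
  hp <- hairpin_preset(t_max = 22000, seed = child_seed(SEED, 608))
  tr <- simulate_overdamped(hp$potential, hp$diffusion, hp$telegraph, hp$config)
  st <- classify_hairpin_states(tr, hp$x_threshold, hp$level_threshold)
  ev <- doublet_transition_times(st, tr)
  uf <- ev$tau[ev$direction == "U+_to_F-"]
  fu <- ev$tau[ev$direction == "F-_to_U+"]
  expect_gte(min(length(uf), length(fu)), 300)
  expect_lt(ks_two_sample(uf, fu)$p_value, 0.05)

  # time reversal swaps the two directions
  st_r <- classify_hairpin_states(time_reverse(tr), hp$x_threshold,
                                  hp$level_threshold)
  ev_r <- doublet_transition_times(st_r, time_reverse(tr))
  expect_equal(sum(ev$direction == "U+_to_F-"), sum(ev_r$direction == "F-_to_U+"))

  # degenerate protocol (equal levels = constant force) is an equilibrium
  # two-state system: folding and unfolding path times are symmetric
  ev_s <- run_transition_protocol(
    hp$potential, hp$diffusion, c(-0.25, 0.25),
    telegraph = telegraph_spec(0, 0.5, offset = hp$level_threshold),
    min_events = 300, dt = 1e-3, x0 = -0.5,
    seed = child_seed(SEED, 609))
  ks_s <- ks_two_sample(ev_s$tau[ev_s$direction == "L_to_R"],
                        ev_s$tau[ev_s$direction == "R_to_L"])
  expect_gt(ks_s$p_value, 0.05)
})
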