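test_that("mean first-passage profile reproduces closed forms and boundary conditions", {
  pr <- mfpt_profile(potential_flat(), 0.15, c(-1.85, 1.85))
  expect_equal(mfpt_at(pr, 0), 3.7^2 / (8 * 0.15), tolerance = 1e-5)
  # absorbing ends
  expect_equal(pr$tau[1], 0, tolerance = 1e-12)
  expect_equal(pr$tau[nrow(pr)], 0, tolerance = 1e-10)
  # parabola tau(x) = (L^2/4 - x^2) / (2D) for free diffusion
  expect_equal(pr$tau, (1.85^2 - pr$x^2) / (2 * 0.15), tolerance = 1e-6)

  # force-sign symmetry of the central mean exit time
  t_plus <- mfpt_at(mfpt_profile(potential_linear(3.3), 0.15, c(-1.85, 1.85)), 0)
  t_minus <- mfpt_at(mfpt_profile(potential_linear(-3.3), 0.15, c(-1.85, 1.85)), 0)
  expect_equal(t_plus, t_minus, tolerance = 1e-9)

  expect_error(mfpt_profile(potential_flat(), diffusion_constant(-1), c(0, 1)))
})

test_that("splitting probabilities match the constant-force formula and sum to one", {
  # free diffusion: linear splitting
  sp0 <- splitting_probability(potential_flat(), 0.15, 0.25, c(-1, 1))
  expect_equal(sp0$P_right, (0.25 + 1) / 2, tolerance = 1e-8)

  # |f| = 3.3 fN over L = 3.7 um: uphill probability 1/(1 + e^{1.485..})
  sp <- splitting_probability(potential_linear(3.3), 0.15, 0, c(-1.85, 1.85))
  p_up <- 1 / (1 + exp(3.3 * 3.7 / (2 * 4.11)))
  expect_equal(sp$P_left, p_up, tolerance = 1e-6)
  expect_equal(sp$P_left + sp$P_right, 1)
  # downhill exit is always the more likely one
  expect_gt(sp$P_right, 0.5)

  expect_error(splitting_probability(potential_flat(), 0.15, 2, c(-1, 1)), "inside")
})

test_that("mean transition time evaluates the double quadrature exactly at U = 0", {
  expect_equal(mean_transition_time(potential_flat(), 0.15, c(0, 1)),
               1 / (6 * 0.15), tolerance = 1e-6)
  # invariance under constant energy offsets
  xg <- seq(-0.6, 0.6, length.out = 101)
  q <- quartic_from_barrier(3, 1, 1)
  tab1 <- potential_tabulated(xg, potential_eval(q, xg))
  tab2 <- potential_tabulated(xg, potential_eval(q, xg) + 7)
  iv <- c(-0.5, 0.5)
  expect_equal(mean_transition_time(tab1, 0.15, iv),
               mean_transition_time(tab2, 0.15, iv), tolerance = 1e-9)
  # invariance under force reversal for a constant tilt
  expect_equal(mean_transition_time(potential_linear(4), 0.15, c(0, 1)),
               mean_transition_time(potential_linear(-4), 0.15, c(0, 1)),
               tolerance = 1e-9)
})

test_that("exit-time densities are normalized, symmetric, and match the series solution", {
  D <- 0.15
  ed <- exit_time_density(potential_flat(), D, 0, c(-1.85, 1.85))
  expect_equal(attr(ed$left, "mass"), 1, tolerance = 1e-3)
  expect_equal(attr(ed$right, "mass"), 1, tolerance = 1e-3)
  # mirror symmetry from a centred start
  expect_equal(ed$left$density, ed$right$density, tolerance = 1e-9)
  # spectral-series oracle for the right-boundary efflux
  keep <- ed$right$t > 0.02
  exact <- 2 * images_right_flux(ed$right$t[keep], L = 3.7, D = D, x0 = 1.85)
  expect_lt(max(abs(ed$right$density[keep] - exact)), 1e-3)
  # first moment agrees with the mean first-passage time
  tau_num <- 0.5 * density_mean(ed$left) + 0.5 * density_mean(ed$right)
  expect_equal(tau_num, 3.7^2 / (8 * D), tolerance = 0.01)

  expect_error(exit_time_density(potential_flat(), D, -1.85, c(-1.85, 1.85)),
               "inside")
})

test_that("uphill and downhill exit densities coincide under constant force", {
  ed <- exit_time_density(potential_linear(3.3), 0.15, 0, c(-1.85, 1.85))
  rel <- max(abs(ed$left$density - ed$right$density)) / max(ed$right$density)
  expect_lt(rel, 1e-3)
})

test_that("exit-density moments weighted by splitting match the MFPT for a landscape", {
  pot <- quartic_from_barrier(2, 1, 1)
  iv <- c(-0.7, 0.7)
  ed <- exit_time_density(pot, 0.15, 0.1, iv)
  tau_d <- ed$splitting$P_left * density_mean(ed$left) +
    ed$splitting$P_right * density_mean(ed$right)
  expect_equal(tau_d, mfpt_at(mfpt_profile(pot, 0.15, iv), 0.1), tolerance = 0.01)
})

test_that("transition-time density has unit mass and the free-diffusion moment", {
  td <- transition_time_density(potential_flat(), 0.15, c(0, 1))
  expect_equal(attr(td, "mass"), 1, tolerance = 1e-3)
  expect_equal(density_mean(td), 1 / (6 * 0.15), tolerance = 0.005)
  expect_true(all(td$density >= 0))
})

test_that("forward and backward transition densities are identical for static landscapes", {
  pot <- quartic_from_barrier(5, 2, 1)
  iv <- c(-0.4, 0.4)
  d1 <- transition_time_density(pot, 0.15, iv, "L_to_R")
  d2 <- transition_time_density(pot, 0.15, iv, "R_to_L")
  d2i <- approx(d2$t, d2$density, xout = d1$t, rule = 2)$y
  expect_lt(max(abs(d1$density - d2i)) / max(d1$density), 1e-3)
  # and the first moment matches the double-quadrature prediction
  expect_equal(density_mean(d1), mean_transition_time(pot, 0.15, iv),
               tolerance = 0.01)
})

test_that("theory and simulation agree on splitting and mean exit times under tilt", {
  set.seed(child_seed(SEED, 401))
  iv <- c(-1.85, 1.85)
  for (f in c(0, 4)) {
    pot <- if (f == 0) potential_flat() else potential_linear(f)
    res <- run_exit_protocol(pot, 0.15, iv, sim_config(200), 700)
    sp <- splitting_probability(pot, 0.15, 0, iv)
    p_hat <- mean(res$side == "right")
    expect_lt(abs(p_hat - sp$P_right), 3 * sqrt(sp$P_right * sp$P_left / 700))
    sm <- summarize_path_times(res$tau)
    expect_lt(abs(sm$mean - mfpt_at(mfpt_profile(pot, 0.15, iv), 0)), 3 * sm$sem)
  }
})
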