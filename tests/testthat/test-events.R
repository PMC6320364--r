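test_that("first-exit detection interpolates the crossing time", {
  tr <- tibble::tibble(t = c(0, 1, 2), x = c(0, 0.3, 0.6))
  ex <- detect_exits(tr, c(-0.5, 0.5))
  expect_equal(as.character(ex$direction), "to_right")
  expect_equal(ex$tau, 1 + (0.5 - 0.3) / (0.6 - 0.3))
  expect_false(ex$censored)

  # monotone path to the left boundary
  tr2 <- tibble::tibble(t = c(0, 1, 2), x = c(0, -0.4, -0.8))
  ex2 <- detect_exits(tr2, c(-0.5, 0.5))
  expect_equal(as.character(ex2$direction), "to_left")
  expect_equal(ex2$tau, 1 + 0.1 / 0.4)

  # trajectory that never leaves is censored
  tr3 <- tibble::tibble(t = 0:3, x = c(0, 0.1, -0.1, 0))
  expect_true(detect_exits(tr3, c(-0.5, 0.5))$censored)

  expect_error(detect_exits(tr, c(-0.1, 0.1), t_start = 1), "inside")
})

test_that("exit times grow when the interval is widened on the same realization", {
  tr <- make_free_traj(t_max = 100, seed = child_seed(SEED, 301))
  widths <- c(0.4, 0.8, 1.2, 1.6)
  taus <- vapply(widths, function(w) detect_exits(tr, c(-w, w))$tau, numeric(1))
  expect_true(all(diff(taus) >= 0))
})

test_that("transition-path detection applies the last-crossing rule", {
  tr <- tibble::tibble(t = 0:4, x = c(-0.6, -0.2, 0.1, 0.3, 0.6))
  ev <- detect_transition_paths(tr, c(-0.5, 0.5))
  expect_equal(nrow(ev), 1)
  expect_equal(as.character(ev$direction), "L_to_R")
  expect_equal(ev$t_start, 0.25)
  expect_equal(ev$tau, 3 + 2 / 3 - 0.25)

  # a return path is not counted
  expect_equal(nrow(detect_transition_paths(
    tibble::tibble(t = 0:2, x = c(-0.6, -0.2, -0.6)), c(-0.5, 0.5))), 0)

  # a recrossing of the start boundary restarts the clock
  tr2 <- tibble::tibble(t = 0:6, x = c(-0.6, -0.2, -0.6, -0.2, 0.1, 0.3, 0.6))
  ev2 <- detect_transition_paths(tr2, c(-0.5, 0.5))
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$t_start, 2.25)
})

test_that("time reversal swaps transition directions with identical durations", {
  tr <- make_free_traj(t_max = 200, seed = child_seed(SEED, 302))
  iv <- c(-0.5, 0.5)
  fwd <- detect_transition_paths(tr, iv)
  bwd <- detect_transition_paths(time_reverse(tr), iv)
  expect_equal(sum(fwd$direction == "L_to_R"), sum(bwd$direction == "R_to_L"))
  expect_equal(sum(fwd$direction == "R_to_L"), sum(bwd$direction == "L_to_R"))
  expect_equal(sort(fwd$tau), sort(bwd$tau), tolerance = 1e-9)
})

test_that("transition events are disjoint and lie inside the data range", {
  tr <- make_free_traj(t_max = 300, seed = child_seed(SEED, 303))
  ev <- detect_transition_paths(tr, c(-0.6, 0.6))
  expect_gt(nrow(ev), 2)
  expect_true(all(ev$tau > 0))
  ord <- order(ev$t_start)
  ends <- ev$t_start[ord] + ev$tau[ord]
  expect_true(all(ends[-length(ends)] <= ev$t_start[ord][-1] + 1e-12))
  expect_true(all(ev$t_start >= tr$t[1] & ends <= tr$t[nrow(tr)]))
})

test_that("path-time summaries follow mean and SEM arithmetic", {
  s <- summarize_path_times(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sem, sd(c(1, 2, 3)) / sqrt(3))
  expect_warning(s1 <- summarize_path_times(5), "single")
  expect_equal(s1$mean, 5)
  expect_true(is.na(s1$sem))
  # duplicating the sample halves the squared SEM
  s2 <- summarize_path_times(rep(c(1, 2, 3), 2))
  expect_equal(s2$mean, 2)
  expect_equal(s2$sem, sd(rep(c(1, 2, 3), 2)) / sqrt(6))
  expect_error(summarize_path_times(numeric(0)), "samples")
})

test_that("KS statistic matches exact enumeration on small samples", {
  expect_equal(ks_two_sample(c(1, 2), c(1.5, 2.5))$statistic, 0.5)
  expect_equal(ks_two_sample(1:3, 4:6)$statistic, 1)
  k0 <- ks_two_sample(1:5, 1:5)
  expect_equal(k0$statistic, 0)
  expect_equal(k0$p_value, 1)

  set.seed(child_seed(SEED, 304))
  for (i in 1:5) {
    a <- round(runif(4), 3)
    b <- round(runif(5), 3)
    orc <- ks_enum_oracle(a, b)
    expect_equal(ks_two_sample(a, b)$statistic, orc$statistic)
  }
  expect_error(ks_two_sample(numeric(0), 1:3), "empty")
})

test_that("asymptotic KS p-values agree with permutation at moderate n", {
  set.seed(child_seed(SEED, 305))
  a <- rexp(60, 1)
  b <- rexp(60, 1.3)
  ks <- ks_two_sample(a, b)
  # permutation reference
  pool <- c(a, b)
  dperm <- replicate(2000, {
    i <- sample(120, 60)
    suppressWarnings(stats::ks.test(pool[i], pool[-i])$statistic)
  })
  p_perm <- mean(dperm >= ks$statistic - 1e-12)
  expect_lt(abs(ks$p_value - p_perm), 0.05)
})

test_that("KS confidence band half-widths invert the Kolmogorov tail", {
  ks <- ks_two_sample(rnorm(50), rnorm(40))
  n_eff <- 50 * 40 / 90
  for (s in c(0.5, 0.05)) {
    lam <- ks$band_halfwidth(s) * sqrt(n_eff)
    k <- 1:100
    expect_equal(2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lam^2)), s,
                 tolerance = 1e-6)
  }
  # the paper-style significance-0.5 band is tighter than the 0.05 band
  expect_lt(ks$band_halfwidth(0.5), ks$band_halfwidth(0.05))
})

test_that("sliding-interval scan is translation invariant for free diffusion", {
  set.seed(child_seed(SEED, 306))
  trs <- lapply(1:4, function(i) make_free_traj(t_max = 500, seed = NULL))
  sc <- scan_interval(trs, window = 1, step = 0.25, x_range = c(-1.8, 1.8))
  expect_true(all(c("p_lr", "p_rl", "mean_lr", "mean_rl") %in% names(sc)))
  expect_gt(nrow(sc), 5)
  # directional symmetry at every placement, pooled over both directions
  ok <- with(sc, abs(mean_lr - mean_rl) <= 3 * sqrt(sem_lr^2 + sem_rl^2))
  expect_gte(mean(ok, na.rm = TRUE), 0.8)
  # probabilities stay within a factor-range across placements (no trend)
  expect_lt(max(sc$p_lr, na.rm = TRUE) / min(sc$p_lr, na.rm = TRUE), 3)

  expect_warning(empty <- scan_interval(trs[[1]], window = 10, step = 1),
                 "wider")
  expect_equal(nrow(empty), 0)
})

test_that("directional path times agree on a static tilted landscape", {
  ev <- run_transition_protocol(potential_linear(2), 0.15, c(-0.5, 0.5),
                                bounds = c(-2, 2), min_events = 400,
                                dt = 1e-3, seed = child_seed(SEED, 307))
  lr <- ev$tau[ev$direction == "L_to_R"]
  rl <- ev$tau[ev$direction == "R_to_L"]
  expect_lt(abs(mean(lr) - mean(rl)),
            3 * sqrt(var(lr) / length(lr) + var(rl) / length(rl)))
})
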