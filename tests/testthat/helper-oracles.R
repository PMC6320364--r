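# Shared fixtures and independent oracles for the test suite.
# One global seed; stage-specific streams derive from it via child_seed().
SEED <- 42L

# Exact two-sample KS oracle by full enumeration of label assignments
# (feasible for n1 + n2 <= 10): statistic from the pooled ECDF grid, exact
# permutation p-value.
ks_enum_oracle <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a)
  stat_of <- function(x, y) {
    g <- sort(unique(c(x, y)))
    ex <- vapply(g, function(v) mean(x <= v), numeric(1))
    ey <- vapply(g, function(v) mean(y <= v), numeric(1))
    max(abs(ex - ey))
  }
  d_obs <- stat_of(a, b)
  idx <- utils::combn(length(pool), n1)
  ds <- apply(idx, 2, function(i) stat_of(pool[i], pool[-i]))
  list(statistic = d_obs, p_exact = mean(ds >= d_obs - 1e-12))
}

# Spectral-series efflux through the right boundary for free diffusion with
# two absorbing boundaries at (0, L), started from a delta at x0.
images_right_flux <- function(t, L, D, x0, n_terms = 400) {
  k <- seq_len(n_terms)
  vapply(t, function(tt) {
    sum(2 * D * pi * k / L^2 * sin(k * pi * x0 / L) * (-1)^(k + 1) *
          exp(-D * (k * pi / L)^2 * tt))
  }, numeric(1))
}

# chi-square statistic of a sample against a Boltzmann law exp(-U/kBT)
boltzmann_chisq <- function(x, potential, n_bins = 20) {
  br <- stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1))
  br[1] <- br[1] - 1e-9
  br[n_bins + 1] <- br[n_bins + 1] + 1e-9
  obs <- as.vector(table(cut(x, br)))
  xx <- seq(br[1], br[n_bins + 1], length.out = 4001)
  w <- exp(-potential_eval(potential, xx))
  Wc <- c(0, cumsum(diff(xx) * (w[-1] + w[-length(w)]) / 2))
  p_exp <- diff(stats::approx(xx, Wc, xout = as.vector(br))$y)
  p_exp <- p_exp / sum(p_exp)
  chi <- sum((obs - length(x) * p_exp)^2 / (length(x) * p_exp))
  stats::pchisq(chi, df = n_bins - 1, lower.tail = FALSE)
}

# short free-diffusion trajectory used by several event tests
make_free_traj <- function(t_max = 50, seed = SEED, D = 0.15, dt = 1e-3) {
  simulate_overdamped(potential_flat(), D,
                      config = sim_config(t_max, dt = dt, bounds = c(-2, 2),
                                          seed = seed))
}
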