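#' Drift and diffusion inference from trajectory displacements
#'
#' Parcels single-step displacements Delta x into spatial bins (assigned by
#' the step's starting position) and fits, per bin, the Gaussian displacement
#' law rho(Delta x) = (4 pi D Delta t)^{-1/2}
#' exp(-(Delta x - Delta t f / gamma)^2 / (4 D Delta t)). The fit is exact
#' moment matching (sample mean and variance), which is the maximum-likelihood
#' solution for a Gaussian: D_hat = var / (2 Delta t) and, eliminating the
#' friction through Einstein-Stokes gamma = kBT / D,
#' f_hat = mean * kBT / (D_hat * Delta t). Standard errors follow from the
#' sampling distributions of the per-bin mean and variance.
#'
#' @param trajs a trajectory or list of trajectories (data frames with
#'   columns `t`, `x`, uniformly sampled).
#' @param bin_edges strictly increasing spatial bin edges (um).
#' @param dt sampling interval (s); defaults to the trajectory's own spacing.
#' @param min_steps bins with fewer steps are flagged (`ok = FALSE`) and get
#'   no estimate.
#' @param units a [units()] object.
#' @return an object of class `pt_dd_fit`: a tibble with one row per bin
#'   (`x`, `f`, `f_se`, `D`, `D_se`, `n`, `ok`) carrying `dt` and `units`
#'   attributes.
#' @export
fit_drift_diffusion <- function(trajs, bin_edges, dt = NULL, min_steps = 50,
                                units = pathtimes::units()) {
  if (is.data.frame(trajs)) trajs <- list(trajs)
  if (any(diff(bin_edges) <= 0)) abort("`bin_edges` must be strictly increasing.")
  steps <- dplyr::bind_rows(lapply(trajs, function(z) {
    dts <- diff(z$t)
    if (diff(range(dts)) > 1e-9 * mean(dts)) abort("trajectories must be uniformly sampled.")
    if (!is.null(dt) && abs(mean(dts) - dt) > 1e-9 * dt) {
      abort("`dt` does not match the trajectory sampling interval.")
    }
    tibble(x0 = z$x[-nrow(z)], dx = diff(z$x), dt = mean(dts))
  }))
  dt <- steps$dt[1]
  steps$bin <- cut(steps$x0, bin_edges, labels = FALSE, include.lowest = TRUE)
  steps <- steps[!is.na(steps$bin), ]
  centers <- (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2
  kBT <- units$kBT

  out <- steps |>
    dplyr::group_by(bin = .data$bin) |>
    dplyr::summarise(n = dplyr::n(), m = mean(.data$dx), v = var(.data$dx),
                     .groups = "drop") |>
    dplyr::mutate(
      ok = .data$n >= min_steps,
      D = ifelse(.data$ok, .data$v / (2 * dt), NA_real_),
      # var(sample variance) = 2 sigma^4 / (n - 1) for Gaussian steps
      D_se = ifelse(.data$ok, .data$v / (2 * dt) * sqrt(2 / (.data$n - 1)), NA_real_),
      f = ifelse(.data$ok, .data$m * kBT / (.data$D * dt), NA_real_),
      f_se = ifelse(.data$ok,
                    kBT / (.data$D * dt) *
                      sqrt(.data$v / .data$n + (.data$m * .data$D_se / .data$D)^2),
                    NA_real_),
      x = centers[.data$bin]
    ) |>
    dplyr::select("x", "f", "f_se", "D", "D_se", "n", "ok") |>
    dplyr::arrange(.data$x)

  structure(out, class = c("pt_dd_fit", class(out)), dt = dt, units = units)
}

#' Force inference from exit counts
#'
#' Inverts the constant-force splitting probability
#' P_right = (1 + exp(-f L / 2 kBT))^{-1}: f_hat = (2 kBT / L)
#' logit(n_right / n), i.e. |f_hat| = (2 kBT / L) log(n_major / n_minor) with
#' the sign pointing toward the majority exit. The confidence interval is the
#' continuity-corrected Wilson binomial interval on the exit fraction mapped
#' through the same monotone transform; the continuity-corrected form is
#' conservative (its exact coverage stays at or above the nominal level for
#' every sample size, rather than oscillating around it). With a zero count
#' the point estimate is infinite (flagged) while the interval still yields a
#' finite inner bound.
#'
#' @param n_left,n_right observed exit counts (total >= 20).
#' @param L interval length (um).
#' @param units a [units()] object.
#' @param conf confidence level of the Wilson interval.
#' @return a one-row tibble: `f`, `conf_low`, `conf_high` (fN), `n_left`,
#'   `n_right`, `finite`.
#' @export
force_from_exit_counts <- function(n_left, n_right, L,
                                   units = pathtimes::units(), conf = 0.95) {
  n <- n_left + n_right
  if (n < 20) abort("need at least 20 exits in total.")
  z <- qnorm(1 - (1 - conf) / 2)
  p <- n_right / n
  lo <- if (n_right == 0) 0 else {
    (2 * n * p + z^2 - 1 -
       z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * (1 - p) + 1))) / (2 * (n + z^2))
  }
  hi <- if (n_left == 0) 1 else {
    (2 * n * p + z^2 + 1 +
       z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * (1 - p) - 1))) / (2 * (n + z^2))
  }
  eps <- .Machine$double.eps
  to_f <- function(q) 2 * units$kBT / L * log(q / (1 - q))
  tibble(
    f = if (n_left == 0) Inf else if (n_right == 0) -Inf else to_f(p),
    conf_low = to_f(min(max(lo, eps), 1 - eps)),
    conf_high = to_f(min(max(hi, eps), 1 - eps)),
    n_left = n_left, n_right = n_right,
    finite = n_left > 0 && n_right > 0
  )
}

#' Reconstruct the potential from a drift-diffusion fit
#'
#' Integrates the estimated force profile from the left end of the fitted
#' region, U(x) = -int f dx (trapezoid), with standard errors accumulated in
#' quadrature along the integration path.
#'
#' @param est a `pt_dd_fit` with contiguous estimated bins.
#' @param units a [units()] object (defaults to the fit's own).
#' @return a tibble with columns `x` (um), `U` (kBT) and `U_se` (kBT).
#' @export
reconstruct_potential <- function(est, units = NULL) {
  stopifnot(inherits(est, "pt_dd_fit"))
  units <- units %||% attr(est, "units")
  est <- est[est$ok, ]
  if (nrow(est) < 2) abort("need at least two estimated bins.")
  U <- potential_from_force(est$x, est$f, units)
  dxs <- diff(est$x)
  seg_var <- (dxs / 2)^2 * (est$f_se[-nrow(est)]^2 + est$f_se[-1]^2) / units$kBT^2
  tibble(x = est$x, U = U$U, U_se = sqrt(c(0, cumsum(seg_var))))
}
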