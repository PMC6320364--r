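#' @keywords internal
as_interval <- function(interval) {
  if (inherits(interval, "pt_interval")) return(unclass(interval))
  if (!is.numeric(interval) || length(interval) != 2 || interval[1] >= interval[2]) {
    abort("`interval` must be c(x_left, x_right) with x_left < x_right.")
  }
  as.double(interval)
}

#' Interval specification
#'
#' A spatial interval `(x_left, x_right)` whose boundaries define exit-path
#' (first passage from inside) and transition-path (boundary-to-boundary)
#' events. Plain numeric `c(x_left, x_right)` is accepted everywhere an
#' interval is expected.
#'
#' @param x_left,x_right boundaries in um, `x_left < x_right`.
#' @export
interval_spec <- function(x_left, x_right) {
  structure(as_interval(c(x_left, x_right)), class = "pt_interval")
}

# All boundary crossings ("touches") of both interval edges, in time order.
# Crossing times are linearly interpolated between straddling samples.
boundary_touches <- function(t, x, interval) {
  touch_one <- function(xb, bnd) {
    s <- x - xb
    n <- length(s)
    up <- which(s[-n] < 0 & s[-1] >= 0)
    dn <- which(s[-n] >= 0 & s[-1] < 0)
    i <- c(up, dn)
    if (!length(i)) {
      return(tibble(t = numeric(0), boundary = character(0), dir = integer(0)))
    }
    frac <- (xb - x[i]) / (x[i + 1] - x[i])
    tibble(t = t[i] + frac * (t[i + 1] - t[i]),
           boundary = bnd,
           dir = rep(c(1L, -1L), c(length(up), length(dn))))
  }
  out <- dplyr::bind_rows(touch_one(interval[1], "L"), touch_one(interval[2], "R"))
  dplyr::arrange(out, .data$t)
}

# Pair consecutive touches of opposite boundaries into direct transitions.
# A touch at L immediately followed (with no intermediate touch of either
# boundary) by a touch at R is an L->R transition starting at the last
# up-crossing of x_left; return paths never produce an (L, R) touch pair.
pair_touches <- function(touches) {
  n <- nrow(touches)
  if (n < 2) {
    return(tibble(direction = factor(character(0), levels = c("L_to_R", "R_to_L")),
                  t_start = numeric(0), tau = numeric(0)))
  }
  b1 <- touches$boundary[-n]; b2 <- touches$boundary[-1]
  d1 <- touches$dir[-n]
  lr <- which(b1 == "L" & b2 == "R" & d1 == 1L)
  rl <- which(b1 == "R" & b2 == "L" & d1 == -1L)
  out <- tibble(
    direction = factor(rep(c("L_to_R", "R_to_L"), c(length(lr), length(rl))),
                       levels = c("L_to_R", "R_to_L")),
    t_start = touches$t[c(lr, rl)],
    tau = touches$t[c(lr, rl) + 1L] - touches$t[c(lr, rl)]
  )
  dplyr::arrange(out, .data$t_start)
}

touch_counts <- function(touches) {
  c(entries_L = sum(touches$boundary == "L" & touches$dir == 1L),
    entries_R = sum(touches$boundary == "R" & touches$dir == -1L))
}

#' Detect the first exit from an interval
#'
#' Follows a trajectory from `t_start` (the position there must be strictly
#' inside the interval) to the first crossing of either boundary; the
#' crossing time is linearly interpolated between samples.
#'
#' @param traj a trajectory data frame with columns `t` and `x`.
#' @param interval `c(x_left, x_right)` or [interval_spec()].
#' @param t_start time from which to watch (s).
#' @return a one-row tibble with columns `direction` (`to_left`/`to_right`,
#'   NA when censored), `tau` (exit-path time, s), `t_start`, `censored`.
#' @export
detect_exits <- function(traj, interval, t_start = 0) {
  interval <- as_interval(interval)
  i0 <- which(traj$t >= t_start)[1]
  if (is.na(i0)) abort("`t_start` beyond the end of the trajectory.")
  x0 <- traj$x[i0]
  if (x0 <= interval[1] || x0 >= interval[2]) {
    abort("trajectory must start strictly inside `interval` at `t_start`.")
  }
  tt <- traj$t[i0:nrow(traj)]; xx <- traj$x[i0:nrow(traj)]
  touches <- boundary_touches(tt, xx, interval)
  if (!nrow(touches)) {
    return(tibble(direction = factor(NA, levels = c("to_left", "to_right")),
                  tau = NA_real_, t_start = t_start, censored = TRUE))
  }
  first <- touches[1, ]
  tibble(
    direction = factor(ifelse(first$boundary == "L", "to_left", "to_right"),
                       levels = c("to_left", "to_right")),
    tau = first$t - t_start, t_start = t_start, censored = FALSE
  )
}

#' Detect direct transition paths across an interval
#'
#' Extracts every uninterrupted boundary-to-boundary segment: an L->R sample
#' spans from the last up-crossing of `x_left` before the first subsequent
#' crossing of `x_right` with no intermediate return to `x_left` (and
#' symmetrically for R->L). Trajectory pieces that return to the boundary
#' they started from are not counted. Events are disjoint in time and
#' returned in time order.
#'
#' @inheritParams detect_exits
#' @return a tibble with columns `direction` (`L_to_R`/`R_to_L`), `t_start`
#'   and `tau` (s); zero rows when no transition occurs.
#' @export
detect_transition_paths <- function(traj, interval) {
  interval <- as_interval(interval)
  pair_touches(boundary_touches(traj$t, traj$x, interval))
}

#' Summarize a set of path times
#'
#' @param tau path-time samples in seconds (or a tibble with a `tau` column).
#' @return a tibble with `n`, `mean` and `sem` (sample SD / sqrt(n); NA and a
#'   warning for a single sample).
#' @export
summarize_path_times <- function(tau) {
  if (is.data.frame(tau)) tau <- tau$tau
  tau <- tau[is.finite(tau)]
  if (!length(tau)) abort("no (finite) path-time samples.")
  if (length(tau) == 1) warn("single sample: SEM undefined.")
  tibble(n = length(tau), mean = mean(tau),
         sem = if (length(tau) > 1) sd(tau) / sqrt(length(tau)) else NA_real_)
}

# inverse of the asymptotic Kolmogorov tail Q(lambda) = 2 sum (-1)^{k-1} e^{-2 k^2 lambda^2}
kolmogorov_tail <- function(lambda) {
  k <- 1:100
  vapply(lambda, function(l) {
    if (l < 0.4) {
      # Jacobi-theta form, fast-converging for small lambda
      cdf <- sqrt(2 * pi) / l * sum(exp(-(2 * k - 1)^2 * pi^2 / (8 * l^2)))
      return(min(1, max(0, 1 - cdf)))
    }
    min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * l^2))))
  }, numeric(1))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-sided two-sample KS statistic with the asymptotic Kolmogorov p-value
#' at effective sample size n1 n2 / (n1 + n2). The returned object carries
#' `band_halfwidth(significance)`, the critical ECDF deviation at a given
#' significance level, for drawing KS confidence bands around cumulative
#' path-time distributions.
#'
#' @param a,b numeric samples (both nonempty; p-values are reliable for
#'   n >= 5 per sample).
#' @return an object of class `pt_ks` with fields `statistic`, `p_value`,
#'   `n1`, `n2` and function `band_halfwidth`.
#' @export
ks_two_sample <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b)) abort("empty sample in KS comparison.")
  kt <- suppressWarnings(ks.test(a, b, exact = FALSE))
  n1 <- length(a); n2 <- length(b)
  n_eff <- n1 * n2 / (n1 + n2)
  structure(list(
    statistic = unname(kt$statistic),
    p_value = unname(kt$p.value),
    n1 = n1, n2 = n2,
    band_halfwidth = function(significance) {
      stopifnot(significance > 0, significance < 1)
      lam <- uniroot(function(l) kolmogorov_tail(l) - significance,
                     c(1e-6, 10), tol = 1e-10)$root
      lam / sqrt(n_eff)
    }
  ), class = "pt_ks")
}

#' @export
print.pt_ks <- function(x, ...) {
  cat(sprintf("<pt_ks> D = %.4f, p = %.4g (n1 = %d, n2 = %d)\n",
              x$statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' Sliding-interval scan of transition statistics
#'
#' Moves a window of fixed width along x and, at each placement, counts
#' direct crossings in both directions across the window, the corresponding
#' transition probabilities (direct crossings per entry at the respective
#' edge), and mean transition-path times with their SEMs.
#'
#' @param trajs a trajectory or list of trajectories (data frames with
#'   columns `t`, `x`).
#' @param window window width (um, > 0).
#' @param step displacement between successive placements (um, > 0).
#' @param x_range range `c(lo, hi)` to scan; defaults to the pooled data
#'   range.
#' @return a tibble with one row per placement: `x_left`, `x_right`,
#'   `x_center`, counts `n_lr`/`n_rl`, entries, probabilities `p_lr`/`p_rl`,
#'   and `mean_lr`/`sem_lr`/`mean_rl`/`sem_rl`. Placements are dropped with a
#'   warning when the window does not fit `x_range`.
#' @export
scan_interval <- function(trajs, window, step = 0.05, x_range = NULL) {
  if (window <= 0 || step <= 0) abort("`window` and `step` must be positive.")
  if (is.data.frame(trajs)) trajs <- list(trajs)
  if (is.null(x_range)) {
    x_range <- range(unlist(lapply(trajs, function(z) range(z$x))))
  }
  if (x_range[2] - x_range[1] < window) {
    warn("window wider than the data range: empty scan.")
    return(tibble(x_left = numeric(0), x_right = numeric(0), x_center = numeric(0),
                  n_lr = integer(0), n_rl = integer(0),
                  entries_L = integer(0), entries_R = integer(0),
                  p_lr = numeric(0), p_rl = numeric(0),
                  mean_lr = numeric(0), sem_lr = numeric(0),
                  mean_rl = numeric(0), sem_rl = numeric(0)))
  }
  starts <- seq(x_range[1], x_range[2] - window, by = step)
  purrr::map_dfr(starts, function(xl) {
    iv <- c(xl, xl + window)
    tt <- purrr::map(trajs, function(z) boundary_touches(z$t, z$x, iv))
    ev <- dplyr::bind_rows(purrr::map(tt, pair_touches))
    cnt <- Reduce(`+`, purrr::map(tt, touch_counts))
    lr <- ev$tau[ev$direction == "L_to_R"]
    rl <- ev$tau[ev$direction == "R_to_L"]
    tibble(
      x_left = iv[1], x_right = iv[2], x_center = mean(iv),
      n_lr = length(lr), n_rl = length(rl),
      entries_L = unname(cnt["entries_L"]), entries_R = unname(cnt["entries_R"]),
      p_lr = ifelse(cnt["entries_L"] > 0, length(lr) / cnt["entries_L"], NA_real_),
      p_rl = ifelse(cnt["entries_R"] > 0, length(rl) / cnt["entries_R"], NA_real_),
      mean_lr = ifelse(length(lr) > 0, mean(lr), NA_real_),
      sem_lr = ifelse(length(lr) > 1, sd(lr) / sqrt(length(lr)), NA_real_),
      mean_rl = ifelse(length(rl) > 0, mean(rl), NA_real_),
      sem_rl = ifelse(length(rl) > 1, sd(rl) / sqrt(length(rl)), NA_real_)
    )
  })
}
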