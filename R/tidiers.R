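#' Tidiers for pathtimes result objects
#'
#' Broom-style methods: `tidy()` returns the per-component table of a result
#' (per-bin estimates, per-alpha sweep rows, KS comparison as one row),
#' `glance()` a one-row summary.
#'
#' @param x a pathtimes result object.
#' @param ... unused.
#' @return a tibble.
#' @name pathtimes-tidiers
NULL

#' @rdname pathtimes-tidiers
#' @export
tidy.pt_ks <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value, n1 = x$n1, n2 = x$n2)
}

#' @rdname pathtimes-tidiers
#' @export
glance.pt_ks <- function(x, ...) tidy(x)

#' @rdname pathtimes-tidiers
#' @export
tidy.pt_dd_fit <- function(x, ...) as_tibble(x)

#' @rdname pathtimes-tidiers
#' @export
glance.pt_dd_fit <- function(x, ...) {
  ok <- x[x$ok, ]
  tibble(
    n_bins = nrow(x), n_estimated = nrow(ok), n_steps = sum(x$n),
    D_mean = mean(ok$D), f_range = diff(range(ok$f)), dt = attr(x, "dt")
  )
}

#' @rdname pathtimes-tidiers
#' @export
tidy.pt_sweep <- function(x, ...) as_tibble(x)

#' @rdname pathtimes-tidiers
#' @export
glance.pt_sweep <- function(x, ...) {
  tibble(
    n_alphas = nrow(x),
    max_abs_asymmetry = max(abs(x$asymmetry)),
    min_ks_p = min(x$ks_p, na.rm = TRUE)
  )
}

#' @rdname pathtimes-tidiers
#' @export
tidy.pt_current <- function(x, ...) x$plaquettes

#' @rdname pathtimes-tidiers
#' @export
glance.pt_current <- function(x, ...) {
  tibble(circulation = x$circulation, score = x$score, se = x$se, z = x$z,
         n_moves = x$n_moves, n_diagonal = x$n_diagonal)
}

#' @rdname pathtimes-tidiers
#' @export
tidy.pt_splitting <- function(x, ...) {
  tibble(P_left = x$P_left, P_right = x$P_right)
}
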