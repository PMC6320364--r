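#' Plot methods
#'
#' ggplot2 `autoplot()` methods for the package's result types: path-time
#' densities (density and cumulative view), occupancy maps in the position x
#' force plane, asymmetry sweeps over the telegraph rate, and drift/diffusion
#' profiles. `plot_potential()` draws a landscape over a range.
#'
#' @param object a pathtimes result object.
#' @param ... unused.
#' @return a ggplot object.
#' @name pathtimes-plots
NULL

#' @rdname pathtimes-plots
#' @param cumulative draw the cumulative distribution instead of the density.
#' @export
autoplot.pt_density <- function(object, cumulative = FALSE, ...) {
  df <- as_tibble(object)
  if (cumulative) {
    df$F <- cumtrapz(df$t, df$density)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$F)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "path time (s)", y = "cumulative probability",
                    title = attr(object, "direction"))
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$density)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "path time (s)", y = "density (1/s)",
                    title = attr(object, "direction"))
  }
}

#' @rdname pathtimes-plots
#' @export
autoplot.pt_occupancy <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$x_mid, y = .data$f_mid, fill = .data$p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "position (um)", y = "total force (fN)",
                  fill = "occupancy")
}

#' @rdname pathtimes-plots
#' @export
autoplot.pt_sweep <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object),
                            cols = c("mean_lr", "mean_rl"),
                            names_to = "direction", values_to = "mean_tau")
  df$sem <- ifelse(df$direction == "mean_lr", df$sem_lr, df$sem_rl)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$alpha, y = .data$mean_tau,
                                   colour = .data$direction)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_tau - .data$sem,
                                          ymax = .data$mean_tau + .data$sem)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "telegraph decorrelation rate alpha (1/s)",
                  y = "mean transition-path time (s)", colour = NULL)
}

#' @rdname pathtimes-plots
#' @export
autoplot.pt_dd_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object[object$ok, ]),
                            cols = c("f", "D"), names_to = "quantity")
  df$se <- ifelse(df$quantity == "f", df$f_se, df$D_se)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$value)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$value - .data$se,
                                          ymax = .data$value + .data$se)) +
    ggplot2::facet_wrap(~quantity, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(f = "force (fN)", D = "diffusion (um^2/s)"))) +
    ggplot2::labs(x = "position (um)", y = NULL)
}

#' @rdname pathtimes-plots
#' @param potential a `pt_potential`.
#' @param range x-range `c(lo, hi)` (um).
#' @param units a [units()] object.
#' @export
plot_potential <- function(potential, range, units = pathtimes::units()) {
  x <- seq(range[1], range[2], length.out = 400)
  ggplot2::ggplot(tibble(x = x, U = potential_eval(potential, x, units)),
                  ggplot2::aes(x = .data$x, y = .data$U)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (um)", y = "U (kBT)")
}
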