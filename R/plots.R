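# ggplot2 views of the main result types.

#' Plot a performance table, optionally with model curves
#'
#' Normalized MSE against delay, one line per set size, with SEM error
#' bars.  Pass fitted objects to overlay their anchored predictions.
#'
#' @param object A [performance_table()].
#' @param ... `stm_fit` objects to overlay (named arguments are ignored).
#' @return A ggplot.
#' @export
autoplot.performance_table <- function(object, ...) {
  fits <- Filter(function(f) inherits(f, "stm_fit"), list(...))
  p <- ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$delay_s, y = .data$mse_norm,
                 colour = factor(.data$set_size))
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mse_norm - .data$sem_norm,
                   ymax = .data$mse_norm + .data$sem_norm),
      width = 0.05
    ) +
    ggplot2::labs(x = "delay (s)", y = "normalized MSE",
                  colour = "set size")
  for (f in fits) {
    kind <- if (inherits(f, "coded_fit")) "coded" else "direct"
    p <- p + ggplot2::geom_line(
      data = mutate(f$predictions, model = kind),
      ggplot2::aes(y = .data$pred, linetype = .data$model)
    )
  }
  p
}

#' Plot a coded-fit error surface and its valley
#'
#' Log-log heat map of the weighted SSE over the `(N, 1/(2*D))` landscape
#' with the per-`N` valley overlaid.
#'
#' @param object An `error_surface` tibble (from [fit_coded()]'s
#'   `$surface`).
#' @param valley Optional valley tibble to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.error_surface <- function(object, valley = NULL, ...) {
  p <- ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$n_channels, y = .data$inv2d,
                 fill = log10(.data$wsse))
  ) +
    ggplot2::geom_raster() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "N (channels)", y = "1/2D (s)",
                  fill = "log10 WSSE")
  if (!is.null(valley)) {
    p <- p + ggplot2::geom_line(
      data = valley,
      ggplot2::aes(x = .data$n_channels, y = .data$inv2d),
      inherit.aes = FALSE, colour = "white"
    )
  }
  p
}

#' Plot valley profile and resource use along the valley
#'
#' @param valley The `$valley` tibble of a [fit_coded()] result.
#' @return A ggplot with WSSE and resource `N/(2*D)` against `N`.
#' @export
plot_valley <- function(valley) {
  long <- tidyr::pivot_longer(valley[c("n_channels", "wsse", "resource")],
                              c("wsse", "resource"),
                              names_to = "quantity")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n_channels,
                                     y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$quantity), scales = "free_y") +
    ggplot2::labs(x = "N (channels)", y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
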