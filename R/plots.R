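#' Raster plot of spike trains
#'
#' @param spikes A [spike_trains] tibble.
#' @param bursts Optional `network_bursts` table shaded behind the raster.
#' @return A ggplot object.
#' @export
plot_raster <- function(spikes, bursts = NULL) {
  p <- ggplot2::ggplot(tibble::as_tibble(spikes),
                       ggplot2::aes(x = .data$time_s,
                                    y = factor(.data$electrode_id)))
  if (!is.null(bursts) && nrow(bursts)) {
    p <- p + ggplot2::geom_rect(
      data = tibble::as_tibble(bursts), inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf),
      fill = "steelblue", alpha = 0.2)
  }
  p + ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(x = "time (s)", y = "electrode",
                  title = "Spike raster") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.spectral_summary <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$freq_hz, .data$psd_uV2_per_hz)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = expression(PSD~(mu*V^2/Hz))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.band_timecourse <- function(object, ...) {
  lab <- sprintf("%g-%g Hz", object$band_lo_hz[1], object$band_hi_hz[1])
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$div_day, .data$log10_ratio)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "days in vitro",
                  y = bquote(log[10]~"power ratio ("*.(lab)*")")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sholl_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$radius_um, .data$intersections)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "radius from soma (um)", y = "intersections",
                  title = "Sholl profile") +
    ggplot2::theme_minimal()
}

#' Plot a neuron morphology in the tracing plane
#'
#' @param morph A `neuron_morphology`.
#' @return A ggplot object.
#' @export
plot_morphology <- function(morph) {
  seg <- neurite_segments(morph)
  ctr <- soma_centroid(morph)
  r <- morph$radius[morph$parent == -1]
  th <- seq(0, 2 * pi, length.out = 90)
  soma <- tibble::tibble(x = ctr["x"] + r * cos(th),
                         y = ctr["y"] + r * sin(th))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1)) +
    ggplot2::geom_polygon(data = soma, ggplot2::aes(.data$x, .data$y),
                          fill = "grey40") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}
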