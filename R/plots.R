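# ggplot2 figures for each result type.

#' Plot methods
#'
#' `autoplot()` methods: phase-binned amplitude profile for a
#' `pac_histogram`, the spectrum in dB for a `band_psd`, adjacency tiles for
#' a `binary_network`, and stacked channel traces for an `eeg_recording`.
#' [plot_comparison()] shows condition means with standard-deviation error
#' bars for a comparison table.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name pacnet-plots
NULL

#' @rdname pacnet-plots
#' @method autoplot pac_histogram
#' @export
autoplot.pac_histogram <- function(object, ...) {
  df <- tidy.pac_histogram(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase_mid, y = .data$p)) +
    ggplot2::geom_col(width = 2 * pi / object$n_bins, fill = "steelblue",
                      colour = "grey20") +
    ggplot2::geom_hline(yintercept = 1 / object$n_bins, linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = c(-pi, -pi / 2, 0, pi / 2, pi),
                                labels = c("-π", "-π/2", "0",
                                           "π/2", "π")) +
    ggplot2::labs(x = "phase (rad)", y = "normalized mean amplitude p(j)",
                  title = "Phase-amplitude distribution") +
    ggplot2::theme_minimal()
}

#' @rdname pacnet-plots
#' @param bands Optional list of [band()] objects shaded on the spectrum.
#' @method autoplot band_psd
#' @export
autoplot.band_psd <- function(object, bands = NULL, ...) {
  df <- tidy.band_psd(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$power_db)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "frequency (Hz)",
                  y = expression(10 %.% log[10] * " PSD (dB re " * mu * V^2 / Hz * ")"),
                  title = "Welch power spectral density") +
    ggplot2::theme_minimal()
  if (!is.null(bands)) {
    shade <- purrr::map_dfr(bands, ~ tibble::tibble(name = .x$name,
                                                    lo = .x$f_lo, hi = .x$f_hi))
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15, fill = "orange")
  }
  p
}

#' @rdname pacnet-plots
#' @method autoplot binary_network
#' @export
autoplot.binary_network <- function(object, ...) {
  n <- length(object$channels)
  df <- tibble::tibble(
    a = factor(rep(object$channels, n), levels = object$channels),
    b = factor(rep(object$channels, each = n), levels = rev(object$channels)),
    edge = as.vector(object$adjacency) == 1L
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   fill = .data$edge)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey92",
                                          `TRUE` = "steelblue")) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Binary network (%s band, threshold %.2f)",
                                  object$band, object$threshold)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5),
                   legend.position = "none")
}

#' @rdname pacnet-plots
#' @param max_channels Cap on the number of traces drawn.
#' @method autoplot eeg_recording
#' @export
autoplot.eeg_recording <- function(object, max_channels = 12L, ...) {
  keep <- object$channels[seq_len(min(max_channels, length(object$channels)))]
  df <- dplyr::filter(as_tibble.eeg_recording(object), .data$channel %in% keep)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2, colour = "grey20") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "time (s)", y = expression("amplitude (" * mu * V * ")"),
                  title = sprintf("%s | %s | %s", object$subject_id,
                                  object$group, object$state)) +
    ggplot2::theme_minimal()
}

#' @rdname pacnet-plots
#' @param comparisons A comparison tibble from [compare_states()] or
#'   [compare_groups()].
#' @export
plot_comparison <- function(comparisons, ...) {
  df <- comparisons |>
    tidyr::pivot_longer(cols = c("mean_a", "mean_b"), names_to = "side",
                        values_to = "mean") |>
    dplyr::mutate(
      condition = ifelse(.data$side == "mean_a", .data$condition_a,
                         .data$condition_b),
      sd = ifelse(.data$side == "mean_a", .data$sd_a, .data$sd_b)
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel, y = .data$mean,
                                   fill = .data$condition)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::facet_wrap(ggplot2::vars(.data$feature_name, .data$band),
                        scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean ± sd") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
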