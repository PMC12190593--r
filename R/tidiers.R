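# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy a phase-amplitude histogram
#'
#' @param x A `pac_histogram`.
#' @param ... Unused.
#' @return One row per phase bin: `bin`, `phase_lo`, `phase_hi`,
#'   `phase_mid`, `mean_amplitude`, `p`, `count`.
#' @method tidy pac_histogram
#' @export
tidy.pac_histogram <- function(x, ...) {
  tibble::tibble(
    bin = seq_len(x$n_bins),
    phase_lo = x$bin_edges[-(x$n_bins + 1L)],
    phase_hi = x$bin_edges[-1L],
    phase_mid = (x$bin_edges[-1L] + x$bin_edges[-(x$n_bins + 1L)]) / 2,
    mean_amplitude = x$mean_amplitude,
    p = x$p,
    count = x$counts
  )
}

#' @rdname tidy.pac_histogram
#' @method tidy mi_result
#' @export
tidy.mi_result <- function(x, ...) {
  tibble::tibble(mi = x$mi, entropy = x$entropy, kl = x$kl, n_bins = x$n_bins)
}

#' @rdname tidy.pac_histogram
#' @method glance mi_result
#' @export
glance.mi_result <- function(x, ...) tidy.mi_result(x)

#' Tidy a Welch spectrum
#'
#' @param x A `band_psd`.
#' @param ... Unused.
#' @return One row per frequency bin: `freq`, `pxx`, `power_db`.
#' @method tidy band_psd
#' @export
tidy.band_psd <- function(x, ...) {
  tibble::tibble(freq = x$freqs, pxx = x$pxx,
                 power_db = 10 * log10(pmax(x$pxx, .Machine$double.xmin)))
}

#' @rdname tidy.band_psd
#' @method glance band_psd
#' @export
glance.band_psd <- function(x, ...) {
  tibble::tibble(segment_count = x$segment_count,
                 segment_length = x$segment_length,
                 window_constant = x$window_constant, fs = x$fs,
                 total_power = sum(x$pxx) * (x$freqs[2] - x$freqs[1]))
}

#' Tidy a correlation matrix into channel pairs
#'
#' @param x A `corr_matrix`.
#' @param ... Unused.
#' @return One row per unordered channel pair: `channel_a`, `channel_b`, `r`.
#' @method tidy corr_matrix
#' @export
tidy.corr_matrix <- function(x, ...) {
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(channel_a = x$channels[idx[, 1L]],
                 channel_b = x$channels[idx[, 2L]],
                 r = x$r[idx])
}

#' Tidy a binary network
#'
#' @param x A `binary_network`.
#' @param ... Unused.
#' @return One row per node: `channel`, `degree`, `clustering`.
#' @method tidy binary_network
#' @export
tidy.binary_network <- function(x, ...) {
  tibble::tibble(channel = x$channels, degree = as.numeric(x$degree),
                 clustering = as.numeric(x$clustering))
}

#' @rdname tidy.binary_network
#' @method glance binary_network
#' @export
glance.binary_network <- function(x, ...) {
  tibble::tibble(n_nodes = length(x$channels), threshold = x$threshold,
                 density = x$density, mean_degree = mean(x$degree),
                 mean_clustering = mean(x$clustering), band = x$band)
}
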