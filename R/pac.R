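# Phase-amplitude coupling by the Kullback-Leibler modulation index.
#
# The fast band's amplitude envelope is averaged within 18 equal phase bins
# of the slow band's instantaneous phase; the normalized bin profile p is
# compared against the uniform distribution. MI = KL(p, uniform) / log(N)
# is 0 for phase-independent amplitude and 1 when all amplitude concentrates
# in a single bin. MI is invariant to the logarithm base and to amplitude
# scaling.

#' Phase-binned mean amplitude histogram
#'
#' Assigns each sample to the phase bin containing its phase (equal-width
#' half-open bins over `[-pi, pi]`; a phase of exactly `pi` falls in the last
#' bin), averages the amplitude within each bin, and normalizes the bin means
#' to the probability-like vector `p`.
#'
#' @param phase Numeric vector of instantaneous phases in radians.
#' @param amplitude Numeric vector of non-negative amplitudes, same length.
#' @param n_bins Number of phase bins, default 18.
#' @return A `pac_histogram`: `bin_edges` (length `n_bins + 1`),
#'   `mean_amplitude` (per-bin, 0 for empty bins), `p` (sums to 1),
#'   `n_bins`, `counts`.
#' @export
phase_amplitude_histogram <- function(phase, amplitude, n_bins = 18L) {
  if (length(phase) != length(amplitude)) {
    stop("phase and amplitude must have equal length", call. = FALSE)
  }
  if (n_bins < 2L) stop("n_bins must be at least 2", call. = FALSE)
  ok <- is.finite(phase) & is.finite(amplitude)
  if (!any(ok)) stop("no finite (phase, amplitude) pairs", call. = FALSE)
  phase <- phase[ok]; amplitude <- amplitude[ok]
  edges <- seq(-pi, pi, length.out = n_bins + 1L)
  idx <- findInterval(phase, edges, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L; idx[idx > n_bins] <- n_bins
  counts <- tabulate(idx, nbins = n_bins)
  sums <- vapply(seq_len(n_bins), function(j) sum(amplitude[idx == j]), 0)
  mean_amp <- ifelse(counts > 0L, sums / pmax(counts, 1L), 0)
  total <- sum(mean_amp)
  if (total <= 0) stop("degenerate histogram: all bin mean amplitudes are zero",
                       call. = FALSE)
  structure(list(bin_edges = edges, mean_amplitude = mean_amp,
                 p = mean_amp / total, n_bins = as.integer(n_bins),
                 counts = counts),
            class = "pac_histogram")
}

#' @export
print.pac_histogram <- function(x, ...) {
  cat(sprintf("<pac_histogram> %d phase bins, %d samples\n",
              x$n_bins, sum(x$counts)))
  invisible(x)
}

#' Modulation index of a phase-amplitude histogram
#'
#' Shannon entropy `H(p) = -sum p log p` (with `0 log 0 = 0`), divergence
#' from uniform `KL = log(N) - H(p)`, and the normalized modulation index
#' `MI = KL / log(N)` in `[0, 1]`. Natural logarithms are used internally;
#' MI is invariant to the base.
#'
#' @param hist A `pac_histogram` (or a bare normalized probability vector).
#' @return An `mi_result`: `mi`, `entropy`, `kl`, `n_bins`.
#' @examples
#' h <- phase_amplitude_histogram(runif(1000, -pi, pi), rep(1, 1000))
#' modulation_index(h)$mi # near 0: amplitude independent of phase
#' @export
modulation_index <- function(hist) {
  if (inherits(hist, "pac_histogram")) {
    p <- hist$p
  } else {
    p <- as.numeric(hist)
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("probability vector must be non-negative and sum to 1", call. = FALSE)
    }
  }
  n <- length(p)
  if (all(p == 0)) stop("degenerate histogram: all p zero", call. = FALSE)
  nz <- p > 0
  H <- -sum(p[nz] * log(p[nz]))
  kl <- log(n) - H
  structure(list(mi = kl / log(n), entropy = H, kl = kl, n_bins = n),
            class = "mi_result")
}

#' @export
print.mi_result <- function(x, ...) {
  cat(sprintf("<mi_result> MI = %.4g (H = %.4g, KL = %.4g, %d bins)\n",
              x$mi, x$entropy, x$kl, x$n_bins))
  invisible(x)
}

circular_shift <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) x else c(x[(n - k + 1L):n], x[1:(n - k)])
}

#' Per-channel modulation index of a recording
#'
#' For every channel: band-pass at the phase band and at the amplitude band,
#' extract analytic phase and envelope, trim the filter edge transients, bin
#' and compute the modulation index. Channel order is preserved.
#'
#' The phase band defaults to delta (0.5--4 Hz) and the amplitude band to
#' gamma (30--50 Hz). Setting `surrogate_shift_s` circularly shifts the
#' amplitude envelope by that many seconds before binning, which destroys
#' genuine coupling and estimates the no-coupling MI floor.
#'
#' @param rec An `eeg_recording` lasting at least 10 cycles of
#'   `phase_band$f_lo`.
#' @param phase_band,amp_band [band()] objects for the slow phase and fast
#'   amplitude oscillations.
#' @param n_bins Number of phase bins, default 18.
#' @param surrogate_shift_s Circular amplitude shift in seconds (default 0 =
#'   intact coupling).
#' @return A tibble with columns `channel`, `feature_name` (`"mi"`), `band`
#'   (`"<phase>-<amp>"`), `value`, plus `entropy` and `kl`.
#' @export
channel_mi <- function(rec, phase_band = delta_band(), amp_band = gamma_band(),
                       n_bins = 18L, surrogate_shift_s = 0) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- ncol(rec$data)
  if (n < 10 * rec$fs / phase_band$f_lo) {
    stop(sprintf("recording must last at least 10 cycles of %g Hz (%g s)",
                 phase_band$f_lo, 10 / phase_band$f_lo), call. = FALSE)
  }
  ph_rec <- bandpass(rec, phase_band)
  am_rec <- bandpass(rec, amp_band)
  trim <- max(attr(ph_rec, "filter_taps"), attr(am_rec, "filter_taps"))
  keep <- (trim + 1L):(n - trim)
  if (length(keep) < n_bins * 10L) {
    stop("too few samples remain after edge trimming", call. = FALSE)
  }
  shift <- as.integer(round(surrogate_shift_s * rec$fs))
  band_label <- paste0(phase_band$name, "-", amp_band$name)
  purrr::map_dfr(rec$channels, function(ch) {
    phase <- analytic_signal(ph_rec$data[ch, ])$phase
    amp <- analytic_signal(am_rec$data[ch, ])$amplitude
    if (shift != 0L) amp <- circular_shift(amp, shift)
    mi <- modulation_index(
      phase_amplitude_histogram(phase[keep], amp[keep], n_bins))
    tibble::tibble(channel = ch, feature_name = "mi", band = band_label,
                   value = mi$mi, entropy = mi$entropy, kl = mi$kl)
  })
}
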