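# Band-pass filtering, analytic phase/amplitude, Welch spectra.
#
# Filters are linear-phase FIR (Hamming-windowed design via signal::fir1)
# applied forward and backward so the net response is zero-phase - a
# prerequisite for meaningful phase-amplitude coupling estimates. The
# forward-backward pass is evaluated in the frequency domain: for a symmetric
# kernel h it equals convolution with conv(h, rev(h)), i.e. multiplication by
# |H(f)|^2, which is far faster than two time-domain passes at the long
# kernels a 0.5 Hz edge demands.

# filter order: 3 cycles of the band's lower edge, rounded to even
fir_taps <- function(fs, f_lo) {
  n <- ceiling(3 * fs / f_lo)
  as.integer(n + n %% 2L)
}

design_bandpass <- function(fs, band, n_taps = fir_taps(fs, band$f_lo)) {
  validate_band(band, fs)
  a <- 0.46
  m <- n_taps + 1L
  w <- (1 - a) - a * cos(2 * pi * seq(0L, m - 1L) / (m - 1L))
  as.numeric(signal::fir1(n_taps, c(band$f_lo, band$f_hi) / (fs / 2),
                          type = "pass", window = w))
}

# zero-phase forward-backward FIR via FFT convolution; returns length(x) samples
fir_filtfilt <- function(x, h) {
  n <- length(x); L <- length(h)
  if (n < L) stop("signal shorter than the filter kernel", call. = FALSE)
  nfft <- stats::nextn(n + 2L * L, 2L)
  H <- stats::fft(c(h, numeric(nfft - L)))
  X <- stats::fft(c(x, numeric(nfft - n)))
  # |H|^2 is the transform of the (acausal, zero-centred) autocorrelation of
  # h, so the circular convolution below is already delay-free
  y <- Re(stats::fft(X * Mod(H)^2, inverse = TRUE)) / nfft
  y[seq_len(n)]
}

#' Zero-phase band-pass filter a recording
#'
#' Applies a linear-phase Hamming-windowed FIR band-pass (order three cycles
#' of the band's lower edge) forward and backward to every channel, so the
#' output is free of phase distortion. Output length equals input length;
#' the first and last `filter_taps` samples carry edge transients and are
#' excluded from phase/amplitude statistics downstream.
#'
#' @param rec An `eeg_recording`.
#' @param band An [band()] with `f_hi` below Nyquist.
#' @param n_taps Filter order override; default three cycles of `f_lo`.
#' @return The filtered `eeg_recording`, with attributes `band` and
#'   `filter_taps`.
#' @export
bandpass <- function(rec, band, n_taps = fir_taps(rec$fs, band$f_lo)) {
  stopifnot(inherits(rec, "eeg_recording"))
  h <- design_bandpass(rec$fs, band, n_taps)
  out <- rec
  out$data <- t(apply(rec$data, 1L, fir_filtfilt, h = h))
  rownames(out$data) <- rec$channels
  attr(out, "band") <- band
  attr(out, "filter_taps") <- n_taps
  out
}

#' Analytic signal: instantaneous phase and amplitude envelope
#'
#' Computes the analytic extension of a band-limited signal by the standard
#' one-sided spectrum construction (Hilbert transform): phase is the argument
#' of the analytic signal in radians, amplitude its modulus. For a pure
#' sinusoid the phase advances linearly at `2*pi*f` and the envelope is
#' constant.
#'
#' @param x Numeric vector, already band-limited.
#' @param fs Sampling rate in Hz (used only for the reliability check).
#' @param band Optional [band()]; when given, inputs shorter than 3 cycles of
#'   `f_lo` trigger a warning and `reliable = FALSE`.
#' @return An `analytic_pair`: list with `phase` (radians), `amplitude`
#'   (non-negative envelope), `reliable`.
#' @export
analytic_signal <- function(x, fs = NULL, band = NULL) {
  n <- length(x)
  reliable <- TRUE
  if (!is.null(band) && !is.null(fs) && n < 3 * fs / band$f_lo) {
    warning("input shorter than 3 cycles of the band's lower edge; ",
            "phase/amplitude estimates are unreliable", call. = FALSE)
    reliable <- FALSE
  }
  X <- stats::fft(x)
  mult <- numeric(n)
  if (n %% 2L == 0L) {
    mult[c(1L, n / 2L + 1L)] <- 1
    mult[2:(n / 2L)] <- 2
  } else {
    mult[1L] <- 1
    mult[2:((n + 1L) / 2L)] <- 2
  }
  z <- stats::fft(X * mult, inverse = TRUE) / n
  structure(list(phase = Arg(z), amplitude = Mod(z), band = band,
                 reliable = reliable),
            class = "analytic_pair")
}

#' Welch power spectral density
#'
#' Averages Hamming-windowed, overlapped segment periodograms. The density is
#' normalized by the window power (`sum(w^2)`) and the sampling rate so that
#' integrating `pxx` over frequency recovers the signal variance; the
#' spectrum is one-sided.
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate in Hz.
#' @param segment_length Samples per segment (default 2 s worth).
#' @param overlap Fractional overlap in `[0, 1)`, default 0.5.
#' @param window_a Hamming-family window constant `a` in
#'   `W(n) = (1 - a) - a cos(2 pi n / (N - 1))`; 0.46 gives the standard
#'   Hamming window.
#' @return A `band_psd` object: `freqs` (Hz, 0 to Nyquist), `pxx`
#'   (power density, microvolt^2/Hz), `segment_count`, `segment_length`,
#'   `window_constant`, `fs`.
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 10, by = 1e-3))
#' psd <- welch_psd(x, fs = 1000)
#' psd$freqs[which.max(psd$pxx)] # 10 Hz
#' @export
welch_psd <- function(x, fs, segment_length = round(2 * fs), overlap = 0.5,
                      window_a = 0.46) {
  n <- length(x)
  M <- as.integer(segment_length)
  if (M > n) stop("segment_length exceeds signal length", call. = FALSE)
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)", call. = FALSE)
  step <- max(1L, as.integer(round(M * (1 - overlap))))
  starts <- seq.int(1L, n - M + 1L, by = step)
  w <- (1 - window_a) - window_a * cos(2 * pi * seq(0L, M - 1L) / (M - 1L))
  U <- sum(w^2)                      # window power normalization
  n_keep <- M %/% 2L + 1L
  acc <- numeric(n_keep)
  for (s in starts) {
    X <- stats::fft(x[s:(s + M - 1L)] * w)
    acc <- acc + Mod(X[1:n_keep])^2
  }
  pxx <- acc / (length(starts) * fs * U)
  # one-sided: double everything except DC (and Nyquist when M is even)
  dbl <- rep(2, n_keep); dbl[1L] <- 1
  if (M %% 2L == 0L) dbl[n_keep] <- 1
  structure(list(freqs = seq.int(0L, n_keep - 1L) * fs / M, pxx = pxx * dbl,
                 segment_count = length(starts), segment_length = M,
                 window_constant = window_a, fs = fs),
            class = "band_psd")
}

#' @export
print.band_psd <- function(x, ...) {
  cat(sprintf("<band_psd> %d segments of %d samples @ %g Hz, %d frequency bins\n",
              x$segment_count, x$segment_length, x$fs, length(x$freqs)))
  invisible(x)
}

#' Band-average log power in dB
#'
#' `10 * log10(scale * mean(pxx))` over the frequency bins falling inside the
#' band (inclusive edges). `scale` is a fixed amplification constant applied
#' before the logarithm; absolute dB levels are only comparable at a common
#' `scale`, differences are scale-free.
#'
#' @param psd A `band_psd` from [welch_psd()].
#' @param band A [band()] within the spectrum's frequency range.
#' @param scale Amplification constant, default 1.
#' @return Scalar band power in dB.
#' @export
band_power_db <- function(psd, band, scale = 1) {
  stopifnot(inherits(psd, "band_psd"))
  sel <- psd$freqs >= band$f_lo & psd$freqs <= band$f_hi
  if (!any(sel)) stop("no frequency bins inside band '", band$name, "'", call. = FALSE)
  10 * log10(scale * mean(psd$pxx[sel]))
}

#' Per-channel band power table for a recording
#'
#' Runs [welch_psd()] on every channel and summarizes each requested band
#' with [band_power_db()].
#'
#' @param rec An `eeg_recording`.
#' @param bands List of [band()] objects.
#' @param segment_length,overlap,window_a,scale Passed to [welch_psd()] and
#'   [band_power_db()].
#' @return A tibble with columns `channel`, `feature_name` (`"band_power_db"`),
#'   `band`, `value`.
#' @export
band_power_table <- function(rec, bands = list(delta_band(), gamma_band()),
                             segment_length = round(2 * rec$fs), overlap = 0.5,
                             window_a = 0.46, scale = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  purrr::map_dfr(rec$channels, function(ch) {
    psd <- welch_psd(rec$data[ch, ], rec$fs, segment_length, overlap, window_a)
    tibble::tibble(
      channel = ch,
      feature_name = "band_power_db",
      band = purrr::map_chr(bands, "name"),
      value = purrr::map_dbl(bands, ~ band_power_db(psd, .x, scale))
    )
  })
}
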