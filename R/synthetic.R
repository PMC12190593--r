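# Synthetic multichannel EEG with ground-truth delta-gamma coupling.
#
# Each channel is a slow (delta) carrier plus a fast (gamma) carrier whose
# envelope is modulated by the slow carrier's phase:
#
#   x(t) = a_delta sin(2 pi f_p t + phi0)
#        + a_gamma [(1 + chi sin(2 pi f_p t + phi0)) / (1 + chi)] sin(2 pi f_a t + phi_g)
#        + 1/f^beta noise
#
# The (1 + chi) normalization keeps the mean gamma envelope independent of
# the coupling depth chi, so coupling and band power can be manipulated
# separately. The delta phase phi0 is shared across a subject's channels
# (one common modulator); gamma phases are channel-private. Inter-channel
# correlation comes from shared 1/f latent sources, one per community.
#
# The slow carrier's frequency additionally drifts as a slow
# Ornstein-Uhlenbeck process (sd freq_drift Hz, 5 s correlation time). A
# strictly periodic modulator would make the surrogate control vacuous -
# circularly shifting the envelope of a periodic signal only rotates the
# preferred phase without weakening the coupling - whereas physiological
# delta has a coherence time of a few cycles. The drift is smooth, so the
# instantaneous phase remains trackable by the Hilbert transform and the
# carrier stays inside the delta band, yet the phase decorrelates over
# multi-second lags. freq_drift = 0 recovers the exact closed-form
# sinusoidal model.

#' Specification for the synthetic EEG generator
#'
#' Defaults emulate the study conditions: 60 channels at 1000 Hz, 150 s per
#' state, delta carrier 2 Hz, gamma carrier 40 Hz, resting coupling depth
#' 0.4 doubled in the task state, and stimulation-group multipliers that
#' lower coupling (x0.8), lower delta amplitude (x0.9) and raise gamma
#' amplitude (x1.15) relative to sham. Carrier amplitudes and the noise
#' level are chosen so that both analysis bands stand at least 10 dB above
#' the 10-20 Hz background and the latent communities separate by at least
#' 0.2 in mean correlation - separability for validation, not
#' physiological amplitude ratios.
#'
#' @param n_channels Number of channels.
#' @param fs Sampling rate, Hz.
#' @param duration_s Length of each recording, seconds.
#' @param f_phase,f_amp Slow (phase) and fast (amplitude) carrier
#'   frequencies, Hz.
#' @param chi Baseline coupling depth in `[0, 1]`.
#' @param a_delta,a_gamma Carrier amplitudes, microvolts.
#' @param freq_drift Standard deviation (Hz) of the slow carrier's
#'   Ornstein-Uhlenbeck frequency drift (5 s correlation time); 0 gives a
#'   strictly periodic modulator.
#' @param noise_exponent Spectral slope beta of the 1/f^beta background.
#' @param noise_scale Noise standard deviation, microvolts.
#' @param n_communities Number of latent sources inducing block-structured
#'   inter-channel correlation.
#' @param mixing Fraction of noise variance carried by the shared community
#'   source, in `[0, 1)`.
#' @param task_chi_mult Multiplier on `chi` in the task state.
#' @param tdcs_chi_mult,tdcs_delta_mult,tdcs_gamma_mult Multipliers applied
#'   to the tdcs group's coupling depth, delta amplitude and gamma
#'   amplitude.
#' @param seed Integer seed; identical specs give identical output.
#' @return A validated `generator_spec` list.
#' @export
generator_spec <- function(n_channels = 60L, fs = 1000, duration_s = 150,
                           f_phase = 2, f_amp = 40, chi = 0.4,
                           a_delta = 10, a_gamma = 22, freq_drift = 0.3,
                           noise_exponent = 1, noise_scale = 8,
                           n_communities = 2L, mixing = 0.9,
                           task_chi_mult = 2, tdcs_chi_mult = 0.8,
                           tdcs_delta_mult = 0.9, tdcs_gamma_mult = 1.15,
                           seed = NULL) {
  spec <- list(n_channels = as.integer(n_channels), fs = fs,
               duration_s = duration_s, f_phase = f_phase, f_amp = f_amp,
               chi = chi, a_delta = a_delta, a_gamma = a_gamma,
               freq_drift = freq_drift,
               noise_exponent = noise_exponent, noise_scale = noise_scale,
               n_communities = as.integer(n_communities), mixing = mixing,
               task_chi_mult = task_chi_mult, tdcs_chi_mult = tdcs_chi_mult,
               tdcs_delta_mult = tdcs_delta_mult,
               tdcs_gamma_mult = tdcs_gamma_mult, seed = seed)
  if (spec$chi < 0 || spec$chi > 1) stop("chi must be in [0, 1]", call. = FALSE)
  if (spec$f_amp <= spec$f_phase) stop("f_amp must exceed f_phase", call. = FALSE)
  if (spec$f_amp >= spec$fs / 2) stop("f_amp violates Nyquist", call. = FALSE)
  if (spec$a_delta < 0 || spec$a_gamma < 0 || spec$noise_scale < 0 ||
      spec$freq_drift < 0) {
    stop("amplitudes must be non-negative", call. = FALSE)
  }
  if (spec$mixing < 0 || spec$mixing >= 1) stop("mixing must be in [0, 1)", call. = FALSE)
  mults <- c(spec$task_chi_mult, spec$tdcs_chi_mult, spec$tdcs_delta_mult,
             spec$tdcs_gamma_mult)
  if (any(mults <= 0)) stop("multipliers must be positive", call. = FALSE)
  structure(spec, class = "generator_spec")
}

# 1/f^beta noise by spectral shaping of white noise; draws from current RNG
pink_noise <- function(n, beta, sd_target) {
  if (sd_target == 0) return(numeric(n))
  X <- stats::fft(stats::rnorm(n))
  k <- seq_len(n) - 1L
  shape <- c(0, pmin(k[-1L], n - k[-1L])^(-beta / 2)) # symmetric: keeps ifft real
  y <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  y * sd_target / stats::sd(y)
}

# slow carrier sin(phi(t)) with smooth OU frequency drift; draws from current RNG
slow_carrier <- function(spec, phi0) {
  n <- round(spec$duration_s * spec$fs)
  if (spec$freq_drift > 0) {
    tau <- 5                                   # drift correlation time, s
    a <- exp(-1 / (spec$fs * tau))
    eps <- stats::rnorm(n, 0, spec$freq_drift * sqrt(1 - a^2))
    df <- stats::filter(eps, a, method = "recursive")
    phi <- phi0 + cumsum(2 * pi * (spec$f_phase + as.numeric(df)) / spec$fs)
  } else {
    phi <- phi0 + 2 * pi * spec$f_phase * seq.int(0L, n - 1L) / spec$fs
  }
  sin(phi)
}

# one coupled channel from the current RNG state; shared_noise is added as-is
gen_channel_core <- function(spec, chi, a_delta, a_gamma, slow,
                             shared_noise = 0, private_sd = spec$noise_scale) {
  t <- seq.int(0L, length(slow) - 1L) / spec$fs
  phi_g <- stats::runif(1, -pi, pi)
  env <- (1 + chi * slow) / (1 + chi)
  x <- a_delta * slow +
    a_gamma * env * sin(2 * pi * spec$f_amp * t + phi_g) +
    shared_noise +
    pink_noise(length(t), spec$noise_exponent, private_sd)
  list(signal = x, phi_g = phi_g)
}

#' Generate one channel with known coupling depth
#'
#' @param spec A [generator_spec()]; `spec$seed`, when non-NULL, makes the
#'   draw reproducible.
#' @param phi0 Slow-carrier phase offset; drawn uniformly when NULL.
#' @return List with `signal` (numeric vector) and the ground-truth manifest
#'   entries `chi`, `a_delta`, `a_gamma`, `phi0`.
#' @export
gen_coupled_channel <- function(spec, phi0 = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  if (is.null(phi0)) phi0 <- stats::runif(1, -pi, pi)
  slow <- slow_carrier(spec, phi0)
  ch <- gen_channel_core(spec, spec$chi, spec$a_delta, spec$a_gamma, slow)
  list(signal = ch$signal, chi = spec$chi, a_delta = spec$a_delta,
       a_gamma = spec$a_gamma, phi0 = phi0)
}

#' Generate a full synthetic study
#'
#' One recording per subject x state. Within a subject, all channels share
#' the delta modulator phase; channels are assigned round-robin to
#' `spec$n_communities` communities, each with a shared 1/f latent source
#' carrying `spec$mixing` of the noise variance (block-structured
#' correlations). The task state multiplies coupling depth by
#' `task_chi_mult`; tdcs-group subjects get `tdcs_chi_mult`,
#' `tdcs_delta_mult` and `tdcs_gamma_mult` applied. Coupling depth is capped
#' at 1.
#'
#' @param spec A [generator_spec()].
#' @param n_subjects_per_group Subjects per group, default 12.
#' @param groups Character vector from `c("wm", "tdcs", "sham")`.
#' @param states Character vector from `c("pre_rest", "task", "post_rest")`.
#' @return List with `recordings` (list of `eeg_recording`) and `manifest`
#'   (tibble of ground-truth parameters per subject x state x channel).
#' @export
gen_study <- function(spec, n_subjects_per_group = 12L,
                      groups = c("wm", "tdcs", "sham"),
                      states = c("pre_rest", "task", "post_rest")) {
  stopifnot(inherits(spec, "generator_spec"), n_subjects_per_group >= 1L)
  groups <- match.arg(groups, several.ok = TRUE)
  states <- match.arg(states, several.ok = TRUE)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n_samp <- round(spec$duration_s * spec$fs)
  channels <- sprintf("CH%02d", seq_len(spec$n_channels))
  community <- rep_len(seq_len(spec$n_communities), spec$n_channels)
  shared_sd <- sqrt(spec$mixing) * spec$noise_scale
  private_sd <- sqrt(1 - spec$mixing) * spec$noise_scale

  recordings <- list()
  manifest <- list()
  for (g in groups) {
    for (s_i in seq_len(n_subjects_per_group)) {
      subject <- sprintf("%s%02d", g, s_i)
      for (st in states) {
        chi <- spec$chi *
          (if (st == "task") spec$task_chi_mult else 1) *
          (if (g == "tdcs") spec$tdcs_chi_mult else 1)
        chi <- min(1, chi)
        a_del <- spec$a_delta * (if (g == "tdcs") spec$tdcs_delta_mult else 1)
        a_gam <- spec$a_gamma * (if (g == "tdcs") spec$tdcs_gamma_mult else 1)
        phi0 <- stats::runif(1, -pi, pi)
        slow <- slow_carrier(spec, phi0)
        sources <- lapply(seq_len(spec$n_communities), function(i) {
          pink_noise(n_samp, spec$noise_exponent, shared_sd)
        })
        data <- matrix(0, spec$n_channels, n_samp)
        phi_g <- numeric(spec$n_channels)
        for (c_i in seq_len(spec$n_channels)) {
          ch <- gen_channel_core(spec, chi, a_del, a_gam, slow,
                                 shared_noise = sources[[community[c_i]]],
                                 private_sd = private_sd)
          data[c_i, ] <- ch$signal
          phi_g[c_i] <- ch$phi_g
        }
        rec_id <- paste(subject, st, sep = "_")
        recordings[[rec_id]] <- recording(data, channels, spec$fs, subject, g, st)
        manifest[[rec_id]] <- tibble::tibble(
          subject_id = subject, group = g, state = st, channel = channels,
          community = community, chi = chi, a_delta = a_del, a_gamma = a_gam,
          phi0 = phi0, phi_gamma = phi_g,
          seed = if (is.null(spec$seed)) NA_integer_ else spec$seed
        )
      }
    }
  }
  list(recordings = recordings, manifest = dplyr::bind_rows(manifest))
}

#' Write a generated study to disk
#'
#' One file per recording (`<subject>_<state>.csv` or `.edf`) plus
#' `manifest.csv` holding the ground-truth parameters and a `file` column
#' pointing at each recording.
#'
#' @param study Result of [gen_study()].
#' @param dir Output directory, created if needed.
#' @param format `"csv"` (lossless) or `"edf"` (16-bit quantized).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, format = c("csv", "edf")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(study$recordings, function(rec) {
    fname <- sprintf("%s_%s.%s", rec$subject_id, rec$state, format)
    write_recording(rec, file.path(dir, fname))
    fname
  }, "")
  idx <- tibble::tibble(
    rec_id = names(study$recordings), file = unname(files),
    fs = vapply(study$recordings, function(r) r$fs, 0)
  )
  manifest <- dplyr::left_join(
    dplyr::mutate(study$manifest,
                  rec_id = paste(.data$subject_id, .data$state, sep = "_")),
    idx, by = "rec_id")
  readr::write_csv(dplyr::select(manifest, -"rec_id"),
                   file.path(dir, "manifest.csv"))
  invisible(dir)
}

#' Read a study written by [write_study()]
#'
#' @param dir Directory containing `manifest.csv` and the recording files.
#' @return List with `recordings` and `manifest`, as from [gen_study()].
#' @export
read_study <- function(dir) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE)
  index <- dplyr::distinct(manifest, .data$subject_id, .data$group,
                           .data$state, .data$file, .data$fs)
  recordings <- purrr::pmap(index, function(subject_id, group, state, file, fs) {
    read_recording(file.path(dir, file), fs = fs, subject_id = subject_id,
                   group = group, state = state)
  })
  names(recordings) <- paste(index$subject_id, index$state, sep = "_")
  list(recordings = recordings, manifest = dplyr::select(manifest, -"file", -"fs"))
}
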