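# shared fixtures: tiny deterministic recordings and a reduced-scale
# generator profile used across test files

make_rec <- function(data, channels = sprintf("CH%02d", seq_len(nrow(data))),
                     fs = 250, ...) {
  recording(data, channels, fs, ...)
}

# reduced-scale study profile: short recordings at a lower sampling rate so
# whole simulated studies run in about a second
reduced_spec <- function(..., n_channels = 4, fs = 250, duration_s = 20) {
  generator_spec(n_channels = n_channels, fs = fs, duration_s = duration_s, ...)
}

sine_rec <- function(freq, fs = 1000, dur = 10, amp = 1, channels = "A") {
  t <- seq.int(0, round(dur * fs) - 1) / fs
  make_rec(rbind(amp * sin(2 * pi * freq * t)), channels, fs = fs)
}
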