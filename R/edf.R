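# Minimal EDF (European Data Format) support: ASCII headers plus little-endian
# int16 samples scaled between a digital and a physical range. One data record
# holding the whole signal is written, which keeps arbitrary durations exact
# without padding. Values survive a round trip to within the 16-bit
# quantization of each channel's physical range.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too long: '", x, "'", call. = FALSE)
  formatC(x, width = -width, flag = " ")
}

# shortest %g representation that fits an 8-char EDF numeric field
edf_num8 <- function(x) {
  for (d in 8:1) {
    s <- formatC(x, digits = d, format = "g", width = 1)
    if (nchar(s) <= 8) return(s)
  }
  stop("cannot format ", x, " into 8 characters", call. = FALSE)
}

write_edf <- function(rec, path) {
  n_sig <- length(rec$channels)
  n_samp <- ncol(rec$data)
  dig_min <- -32768; dig_max <- 32767

  # per-channel physical range; the ascii-rounded value is what the reader
  # will see, so quantize against the rounded range for exact consistency
  pmin_s <- pmax_s <- character(n_sig)
  pmin <- pmax <- numeric(n_sig)
  for (i in seq_len(n_sig)) {
    lo <- min(rec$data[i, ]); hi <- max(rec$data[i, ])
    if (hi <= lo) hi <- lo + 1
    pmin_s[i] <- edf_num8(lo); pmax_s[i] <- edf_num8(hi)
    pmin[i] <- as.numeric(pmin_s[i]); pmax[i] <- as.numeric(pmax_s[i])
    if (pmax[i] <= pmin[i]) { # ascii rounding collapsed the range
      pmax_s[i] <- edf_num8(pmin[i] + 1)
      pmax[i] <- as.numeric(pmax_s[i])
    }
  }

  header_bytes <- 256L + 256L * n_sig
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)

  put(edf_pad("0", 8))
  put(edf_pad(rec$subject_id, 80))
  put(edf_pad(paste(rec$group, rec$state), 80))
  put(edf_pad("01.01.00", 8))
  put(edf_pad("00.00.00", 8))
  put(edf_pad(header_bytes, 8))
  put(edf_pad("", 44))
  put(edf_pad(1, 8))                         # one data record
  put(edf_pad(edf_num8(n_samp / rec$fs), 8)) # record duration in seconds
  put(edf_pad(n_sig, 4))

  put(paste(vapply(rec$channels, edf_pad, "", width = 16), collapse = ""))
  put(strrep(" ", 80 * n_sig))               # transducer
  put(paste(rep(edf_pad("uV", 8), n_sig), collapse = ""))
  put(paste(vapply(pmin_s, edf_pad, "", width = 8), collapse = ""))
  put(paste(vapply(pmax_s, edf_pad, "", width = 8), collapse = ""))
  put(paste(rep(edf_pad(dig_min, 8), n_sig), collapse = ""))
  put(paste(rep(edf_pad(dig_max, 8), n_sig), collapse = ""))
  put(strrep(" ", 80 * n_sig))               # prefiltering
  put(paste(rep(edf_pad(n_samp, 8), n_sig), collapse = ""))
  put(strrep(" ", 32 * n_sig))

  for (i in seq_len(n_sig)) {
    scale <- (pmax[i] - pmin[i]) / (dig_max - dig_min)
    dig <- round((rec$data[i, ] - pmin[i]) / scale) + dig_min
    writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  get <- function(n) trimws(readChar(con, n, useBytes = TRUE))

  get(8); subject <- get(80); get(80); get(8); get(8)
  get(8); get(44)
  n_rec <- as.integer(get(8))
  rec_dur <- as.numeric(get(8))
  n_sig <- as.integer(get(4))
  if (is.na(n_sig) || n_sig < 1L) stop("not a valid EDF file: '", path, "'", call. = FALSE)

  field <- function(w) vapply(seq_len(n_sig), function(i) get(w), "")
  labels <- field(16); field(80); field(8)
  pmin <- as.numeric(field(8)); pmax <- as.numeric(field(8))
  dmin <- as.numeric(field(8)); dmax <- as.numeric(field(8))
  field(80)
  spr <- as.integer(field(8))   # samples per record, per signal
  field(32)

  chunks <- vector("list", n_sig)
  for (i in seq_len(n_sig)) chunks[[i]] <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(n_sig)) {
      chunks[[i]][[r]] <- readBin(con, "integer", n = spr[i], size = 2L,
                                  signed = TRUE, endian = "little")
    }
  }
  data <- t(vapply(seq_len(n_sig), function(i) {
    dig <- unlist(chunks[[i]])
    pmin[i] + (dig - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
  }, numeric(n_rec * spr[1])))

  list(channels = labels, fs = spr[1] / rec_dur, data = data, subject = subject)
}
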