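#' Define a frequency band
#'
#' A band is a named half-open frequency interval used for filtering, band
#' power, phase extraction and network construction. The study defaults are
#' delta (0.5--4 Hz) and gamma (30--50 Hz).
#'
#' @param name Character label, e.g. `"delta"`.
#' @param f_lo,f_hi Band edges in Hz, `0 < f_lo < f_hi`.
#' @return An object of class `eeg_band`.
#' @examples
#' band("delta", 0.5, 4)
#' @export
band <- function(name, f_lo, f_hi) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(f_lo) || !is.finite(f_hi) || f_lo <= 0 || f_hi <= f_lo) {
    stop("band edges must satisfy 0 < f_lo < f_hi", call. = FALSE)
  }
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi), class = "eeg_band")
}

#' @rdname band
#' @export
delta_band <- function() band("delta", 0.5, 4)

#' @rdname band
#' @export
gamma_band <- function() band("gamma", 30, 50)

#' @export
print.eeg_band <- function(x, ...) {
  cat(sprintf("<band> %s: %g-%g Hz\n", x$name, x$f_lo, x$f_hi))
  invisible(x)
}

# check a band against a sampling rate at time of use
validate_band <- function(band, fs) {
  if (band$f_hi >= fs / 2) {
    stop(sprintf("band '%s' upper edge %g Hz is at or above Nyquist (%g Hz)",
                 band$name, band$f_hi, fs / 2), call. = FALSE)
  }
  invisible(band)
}
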