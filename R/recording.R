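#' Construct a multichannel EEG recording
#'
#' The atomic analysis unit: one subject in one state. Holds a channels x
#' samples matrix in microvolts plus metadata. Channel order is preserved by
#' every downstream per-channel output.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param channels Character vector of unique channel labels (10-10 style),
#'   one per row of `data`.
#' @param fs Sampling rate in Hz.
#' @param subject_id Subject identifier.
#' @param group One of `"wm"`, `"tdcs"`, `"sham"`.
#' @param state One of `"pre_rest"`, `"task"`, `"post_rest"`.
#' @return An object of class `eeg_recording`.
#' @examples
#' rec <- recording(matrix(rnorm(300), 3), c("Fz", "Cz", "Pz"), fs = 100,
#'                  subject_id = "s01", group = "wm", state = "task")
#' rec
#' @export
recording <- function(data, channels, fs, subject_id = "unknown",
                      group = c("wm", "tdcs", "sham"),
                      state = c("pre_rest", "task", "post_rest")) {
  group <- match.arg(group)
  state <- match.arg(state)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  channels <- as.character(channels)
  if (nrow(data) != length(channels)) {
    stop("data row count must equal the number of channel labels", call. = FALSE)
  }
  if (anyDuplicated(channels)) {
    stop("duplicate channel labels: ",
         paste(unique(channels[duplicated(channels)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a positive number", call. = FALSE)
  }
  if (!all(is.finite(data))) stop("recording contains non-finite samples", call. = FALSE)
  rownames(data) <- channels
  structure(
    list(subject_id = subject_id, group = group, state = state,
         fs = fs, channels = channels, data = data),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s | %s | %s\n", x$subject_id, x$group, x$state))
  cat(sprintf("  %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Convert a recording to a long tibble
#'
#' @param x An `eeg_recording`.
#' @param ... Unused.
#' @return A tibble with columns `channel`, `time_s`, `value`.
#' @method as_tibble eeg_recording
#' @export
as_tibble.eeg_recording <- function(x, ...) {
  tibble::tibble(
    channel = rep(x$channels, each = ncol(x$data)),
    time_s = rep(seq.int(0L, ncol(x$data) - 1L) / x$fs, times = length(x$channels)),
    value = as.vector(t(x$data))
  )
}

#' Read a recording from EDF or delimited text
#'
#' Delimited input is comma-separated with a header row of channel labels and
#' samples as rows (channels as columns); the sampling rate must then be
#' supplied via `fs`. EDF input carries labels and sampling rate in its
#' header.
#'
#' @param path Path to a `.edf` file or a CSV matrix.
#' @param fs Sampling rate in Hz, required for delimited input. If given for
#'   EDF input it is checked against the header.
#' @param subject_id,group,state Metadata attached to the recording.
#' @return An `eeg_recording`.
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, fs = NULL, subject_id = "unknown",
                           group = "wm", state = "pre_rest") {
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    edf <- read_edf(path)
    if (!is.null(fs) && abs(fs - edf$fs) > 1e-9) {
      stop(sprintf("fs mismatch: header says %g Hz, metadata says %g Hz", edf$fs, fs),
           call. = FALSE)
    }
    recording(edf$data, edf$channels, edf$fs, subject_id, group, state)
  } else {
    if (is.null(fs)) stop("fs is required for delimited input", call. = FALSE)
    # base read.csv parses via strtod, which inverts readr's shortest-digit
    # output exactly; vroom's fast parser can be off by one ulp
    df <- tryCatch(
      utils::read.csv(path, check.names = FALSE, colClasses = "numeric"),
      error = function(e) stop("non-numeric cells in '", path, "'",
                               call. = FALSE))
    mat <- as.matrix(df)
    if (!is.numeric(mat) || anyNA(mat)) {
      stop("non-numeric cells in '", path, "'", call. = FALSE)
    }
    recording(t(mat), colnames(df), fs, subject_id, group, state)
  }
}

#' Write a recording to EDF or delimited text
#'
#' The delimited dialect is the mirror of [read_recording()]: header row of
#' channel labels, one column per channel, samples as rows. EDF output uses
#' 16-bit quantization over each channel's observed physical range.
#'
#' @param rec An `eeg_recording`.
#' @param path Destination; format chosen by extension (`.edf` vs anything else).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    write_edf(rec, path)
  } else {
    df <- as.data.frame(t(rec$data))
    colnames(df) <- rec$channels
    # readr writes the shortest representation that round-trips doubles
    # exactly, so CSV recordings reload bit-identically
    readr::write_csv(df, path)
  }
  invisible(path)
}

#' Re-reference a recording to the mean of reference channels
#'
#' Subtracts the sample-wise mean of the reference channels (typically the
#' mastoids M1 and M2) from every other channel, then drops the reference
#' channels: after subtraction they carry only the negated reference mean and
#' would be redundant. The average of the listed references is used.
#'
#' @param rec An `eeg_recording`.
#' @param ref_labels Character vector of reference channel labels, all present
#'   in `rec$channels`.
#' @return An `eeg_recording` without the reference channels.
#' @export
rereference <- function(rec, ref_labels = c("M1", "M2")) {
  stopifnot(inherits(rec, "eeg_recording"))
  missing <- setdiff(ref_labels, rec$channels)
  if (length(missing)) {
    stop("reference channels not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ref <- colMeans(rec$data[ref_labels, , drop = FALSE])
  keep <- setdiff(rec$channels, ref_labels)
  if (!length(keep)) {
    out <- rec$data[0, , drop = FALSE]
  } else {
    out <- sweep(rec$data[keep, , drop = FALSE], 2L, ref, "-")
  }
  recording(out, keep, rec$fs, rec$subject_id, rec$group, rec$state)
}

#' Write a long-format feature table to CSV
#'
#' One row per subject x state x channel x feature with the fixed column
#' order `subject_id, group, state, channel, feature_name, band, value`.
#' Written files round-trip losslessly through [read_feature_table()].
#'
#' @param table A study-table tibble (see [extract_features()]).
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  cols <- c("subject_id", "group", "state", "channel", "feature_name", "band", "value")
  if (!nrow(table)) stop("feature table is empty", call. = FALSE)
  missing <- setdiff(cols, names(table))
  if (length(missing)) {
    stop("feature table lacks columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  readr::write_csv(table[cols], path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  cls <- c(subject_id = "character", group = "character", state = "character",
           channel = "character", feature_name = "character",
           band = "character", value = "numeric")
  tibble::as_tibble(utils::read.csv(path, colClasses = cls))
}
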