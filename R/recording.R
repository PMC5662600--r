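# TimeSeriesRecording: the multichannel voltage container used throughout.

#' Create a multichannel time-series recording
#'
#' A thin container for a multichannel intracranial EEG trace: a numeric
#' matrix with one column per channel, a sampling rate, channel labels and
#' units. All analysis functions in the package accept either a recording or
#' a bare numeric vector/matrix plus `fs`.
#'
#' @param data numeric matrix, samples x channels (a vector is treated as one
#'   channel).
#' @param fs sampling rate, Hz.
#' @param channels character vector of channel labels; defaults to
#'   `"ch1", "ch2", ...`.
#' @param units amplitude units label, default `"uV"`.
#' @param meta free-form list of provenance (stimulation parameters, injected
#'   artifact description, outlier epochs, ...).
#' @return an object of class `ts_recording`.
#' @examples
#' rec <- ts_recording(matrix(rnorm(1024), ncol = 2), fs = 512)
#' rec
#' @export
ts_recording <- function(data, fs, channels = NULL, units = "uV", meta = list()) {
  if (is.vector(data)) data <- matrix(data, ncol = 1L)
  if (!is.matrix(data) || !is.numeric(data))
    stop_field("'data' must be a numeric samples x channels matrix")
  check_scalar_num(fs, "fs", lower = .Machine$double.eps)
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(data)))
  if (length(channels) != ncol(data))
    stop_field("'channels' length (%d) != number of columns (%d)",
               length(channels), ncol(data))
  colnames(data) <- channels
  structure(list(data = data, fs = fs, channels = channels,
                 units = units, meta = meta),
            class = "ts_recording")
}

#' @export
print.ts_recording <- function(x, ...) {
  cat(sprintf("<ts_recording> %d channels x %d samples @ %g Hz (%.1f s), units %s\n",
              ncol(x$data), nrow(x$data), x$fs, nrow(x$data) / x$fs, x$units))
  if (length(x$meta)) cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ts_recording <- function(x) dim(x$data)

n_samples <- function(rec) nrow(rec$data)

#' Duration of a recording in seconds
#' @param rec a `ts_recording`.
#' @return duration, seconds.
#' @export
rec_duration <- function(rec) nrow(rec$data) / rec$fs

# Coerce recording-or-matrix-or-vector into (matrix, fs).
as_signal_matrix <- function(x, fs = NULL) {
  if (inherits(x, "ts_recording")) return(list(data = x$data, fs = x$fs))
  if (is.null(fs)) stop_field("'fs' is required when the input is not a ts_recording")
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  list(data = x, fs = fs)
}

#' Write / read a recording as tab-separated text
#'
#' Plain-text serialization: one `time` column plus one column per channel;
#' sampling rate and units are stored in a `#`-prefixed header line, so the
#' file round-trips losslessly through [read_recording_tsv()].
#'
#' @param rec a `ts_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording_tsv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g units=%s", rec$fs, rec$units), con)
  df <- data.frame(time = (seq_len(nrow(rec$data)) - 1) / rec$fs, rec$data,
                   check.names = FALSE)
  utils::write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_tsv
#' @param path input file path.
#' @export
read_recording_tsv <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec("fs=([0-9.eE+-]+) units=(\\S+)", hdr))[[1L]]
  if (length(m) != 3L) stop_field("missing '# fs=... units=...' header in %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE)
  ts_recording(as.matrix(df[, -1L, drop = FALSE]), fs = as.numeric(m[2L]),
               channels = colnames(df)[-1L], units = m[3L])
}

#' Write an events table (BIDS-style onset/duration/label TSV)
#'
#' @param events data.frame with at least `onset` and `duration` columns
#'   (seconds); extra columns are preserved.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  if (!all(c("onset", "duration") %in% names(events)))
    stop_field("events must have 'onset' and 'duration' columns")
  utils::write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
}
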