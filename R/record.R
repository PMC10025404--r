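#' Multichannel frontal EEG record
#'
#' The container every analysis stage consumes: a channels-by-samples matrix in
#' microvolts plus the sampling rate. Synthetic records additionally carry the
#' generator's ground-truth annotations (phase plan, planted suppression and
#' artifact intervals, true emergence markers), which the test suite uses as an
#' oracle; records read from disk have `annotations = NULL`.
#'
#' @param samples numeric matrix, one row per channel (microvolts).
#' @param fs sampling rate in Hz (>= 128).
#' @param channels character vector of channel labels, one per row.
#' @param annotations optional list of ground-truth annotations.
#'
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(samples, fs,
                       channels = c("F7", "Fp1", "Fp2", "F8"),
                       annotations = NULL) {
  samples <- as.matrix(samples)
  if (nrow(samples) != length(channels))
    abort("`samples` must have one row per channel label.")
  if (!is.numeric(fs) || length(fs) != 1 || fs < 128)
    abort("`fs` must be a single sampling rate >= 128 Hz.")
  structure(
    list(samples = samples, fs = fs, channels = channels,
         annotations = annotations),
    class = "eeg_record"
  )
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %d channels (%s), %.1f s @ %g Hz%s\n",
              nrow(x$samples), paste(x$channels, collapse = ", "),
              record_duration(x), x$fs,
              if (is.null(x$annotations)) "" else ", annotated"))
  invisible(x)
}

#' Record duration in seconds
#' @param record an [eeg_record()].
#' @return Duration in seconds.
#' @export
record_duration <- function(record) ncol(record$samples) / record$fs

#' Sample times of a record
#' @param record an [eeg_record()].
#' @return Numeric vector of sample times (s), starting at 0.
#' @export
record_times <- function(record) (seq_len(ncol(record$samples)) - 1) / record$fs

#' Channel-averaged broadband signal
#'
#' Plain mean across the four frontal channels; this is the broadband trace
#' whose envelope width drives the iso-electric suppression thresholds.
#'
#' @param record an [eeg_record()].
#' @return Numeric vector (microvolts).
#' @export
channel_average <- function(record) colMeans(record$samples)

#' Read / write EEG records as delimited text
#'
#' Plain-text interchange format: a one-line header `# fs=<Hz>` followed by a
#' comma-separated table with one column per channel, one row per sample
#' (microvolts). Annotations are not serialized.
#'
#' @param record an [eeg_record()].
#' @param path file path.
#' @return `write_eeg_delim()` returns `path` invisibly; `read_eeg_delim()`
#'   returns an [eeg_record()].
#' @export
write_eeg_delim <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", record$fs), con)
  df <- as.data.frame(t(record$samples))
  names(df) <- record$channels
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_eeg_delim
#' @export
read_eeg_delim <- function(path) {
  header <- readLines(path, n = 1)
  if (!grepl("^#\\s*fs=", header))
    abort("File does not start with a `# fs=<Hz>` header line.")
  fs <- as.numeric(sub("^#\\s*fs=", "", header))
  df <- readr::read_csv(path, skip = 1, show_col_types = FALSE,
                        progress = FALSE)
  eeg_record(t(as.matrix(df)), fs = fs, channels = names(df))
}
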