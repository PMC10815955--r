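#' Construct a continuous multichannel EEG recording
#'
#' @param data Numeric matrix, samples x channels, amplitudes in microvolts.
#' @param fs Sampling rate, Hz.
#' @param channels Channel labels.
#' @param start_time Time of the first sample, seconds.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channels = colnames(data),
                          start_time = 0) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  check_number(fs, "fs", min = 0, strict_min = TRUE)
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(data)))
  if (length(channels) != ncol(data)) {
    stop_input("number of channel labels must match the number of data columns")
  }
  colnames(data) <- channels
  structure(
    list(data = data, fs = fs, channels = channels, start_time = start_time),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channel(s) [%s], %d samples @ %g Hz (%.1f s from t=%g)\n",
    length(x$channels), paste(x$channels, collapse = ", "),
    nrow(x$data), x$fs, nrow(x$data) / x$fs, x$start_time
  ))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec An [eeg_recording()].
#' @export
rec_duration <- function(rec) nrow(rec$data) / rec$fs

#' @export
as_tibble.eeg_recording <- function(x, ...) {
  out <- tibble::as_tibble(x$data)
  out <- dplyr::mutate(out,
    time_s = x$start_time + (dplyr::row_number() - 1) / x$fs,
    .before = 1
  )
  out
}

#' Construct a stimulus-onset event series
#'
#' @param onset_s Strictly increasing stimulus-onset times, seconds.
#' @return A tibble with one `onset_s` column (class `event_series`).
#' @export
event_series <- function(onset_s) {
  onset_s <- as.numeric(onset_s)
  if (length(onset_s) == 0) stop_input("event series must contain >= 1 onset")
  if (is.unsorted(onset_s, strictly = TRUE)) {
    stop_input("event onsets must be strictly increasing")
  }
  out <- tibble(onset_s = onset_s)
  class(out) <- c("event_series", class(out))
  out
}
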