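# Epoching and amplitude-based rejection. An epoch_set keeps ALL extracted
# epochs together with a rejection mask and reason codes, so the audit trail
# (how many epochs each rule removed) survives the pipeline.

new_epoch_set <- function(data, fs, window, channels, rejected = NULL,
                          reason = NULL, n_dropped_events = 0L,
                          offset_corrected = FALSE) {
  stopifnot(length(dim(data)) == 3L)
  n_ep <- dim(data)[2]
  structure(
    list(
      data = data, # [sample, epoch, channel]
      fs = fs, window = window, channels = channels,
      times = window[1] + (seq_len(dim(data)[1]) - 1) / fs,
      rejected = rejected %||% rep(FALSE, n_ep),
      reason = reason %||% rep(NA_character_, n_ep),
      n_dropped_events = n_dropped_events,
      offset_corrected = offset_corrected
    ),
    class = "epoch_set"
  )
}

#' Construct an epoch set from an array
#'
#' Builds an `epoch_set` directly from stimulus-locked (or fixed) segments,
#' e.g. epochs produced outside this package or in tests.
#'
#' @param data Numeric `[sample, epoch, channel]` array in microvolts.
#' @param fs Sampling rate, Hz.
#' @param window `(t_min, t_max)` seconds relative to the alignment point;
#'   must match the sample count.
#' @param channels Channel labels.
#' @return An `epoch_set`.
#' @export
epoch_set <- function(data, fs, window, channels = NULL) {
  if (length(dim(data)) == 2L) data <- array(data, c(dim(data), 1L))
  if (length(dim(data)) != 3L) {
    stop_input("`data` must be a [sample, epoch, channel] array")
  }
  check_number(fs, "fs", min = 0, strict_min = TRUE)
  if (round((window[2] - window[1]) * fs) != dim(data)[1]) {
    stop_input("window length inconsistent with sample count at this fs")
  }
  channels <- channels %||% paste0("ch", seq_len(dim(data)[3]))
  new_epoch_set(data, fs, window, channels)
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %d epochs x %d samples x %d channel(s), window [%g, %g] s @ %g Hz; %d rejected, %d event(s) dropped\n",
    n_epochs(x), dim(x$data)[1], dim(x$data)[3], x$window[1], x$window[2],
    x$fs, sum(x$rejected), x$n_dropped_events
  ))
  invisible(x)
}

#' Epoch-set accessors
#'
#' @param es An `epoch_set`.
#' @return `n_epochs()`: total epochs; `n_retained()`: epochs surviving all
#'   rejection rules; `retained_data()`: the `[sample, epoch, channel]` array
#'   restricted to retained epochs.
#' @export
n_epochs <- function(es) dim(es$data)[2]

#' @rdname n_epochs
#' @export
n_retained <- function(es) sum(!es$rejected)

#' @rdname n_epochs
#' @export
retained_data <- function(es) es$data[, !es$rejected, , drop = FALSE]

#' @export
as_tibble.epoch_set <- function(x, ...) {
  dims <- dim(x$data)
  tibble(
    time_s = rep(x$times, times = dims[2] * dims[3]),
    epoch = rep(rep(seq_len(dims[2]), each = dims[1]), times = dims[3]),
    channel = rep(x$channels, each = dims[1] * dims[2]),
    value = as.vector(x$data),
    rejected = rep(rep(x$rejected, each = dims[1]), times = dims[3])
  )
}

#' Cut stimulus-locked epochs from a continuous recording
#'
#' Extracts one fixed-length segment per stimulus onset, covering
#' `window` seconds relative to the onset (default `[-0.5, +1.0]` s, i.e.
#' 1.5-s epochs starting 500 ms before the trigger). Events whose window
#' extends beyond the recording are dropped (not zero-padded, which would
#' corrupt wavelet edges) and counted.
#'
#' @param rec An [eeg_recording()].
#' @param events An [event_series()] (or tibble with `onset_s`).
#' @param window `(t_min, t_max)` seconds relative to each onset.
#' @return An `epoch_set`; epoch `i` is aligned so relative time 0 maps to
#'   onset `i`.
#' @export
extract_epochs <- function(rec, events, window = c(-0.5, 1.0)) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (window[2] <= window[1]) stop_config("epoch window must have t_max > t_min")
  n_samp <- round((window[2] - window[1]) * rec$fs)
  onsets <- events$onset_s
  starts <- round((onsets - rec$start_time + window[1]) * rec$fs) + 1L
  ok <- starts >= 1L & (starts + n_samp - 1L) <= nrow(rec$data)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    inform(sprintf("extract_epochs: dropped %d event(s) whose window falls outside the recording", n_dropped))
  }
  starts <- starts[ok]
  if (length(starts) == 0) stop_input("no event window fits inside the recording")
  n_ch <- ncol(rec$data)
  idx <- as.vector(outer(seq_len(n_samp) - 1L, starts, `+`))
  data <- array(0, c(n_samp, length(starts), n_ch))
  for (ch in seq_len(n_ch)) {
    data[, , ch] <- rec$data[idx, ch]
  }
  new_epoch_set(data, rec$fs, window, rec$channels,
                n_dropped_events = as.integer(n_dropped))
}

#' Split a recording into fixed-length contiguous epochs
#'
#' Non-overlapping `epoch_s`-second segments from the start of the recording
#' (default 4 s, the quantitative-EEG segmentation); any remainder shorter
#' than one epoch is discarded and counted.
#'
#' @param rec An [eeg_recording()].
#' @param epoch_s Epoch length, seconds.
#' @return An `epoch_set` with window `[0, epoch_s]` (times relative to each
#'   epoch's own start).
#' @export
segment_epochs <- function(rec, epoch_s = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  check_number(epoch_s, "epoch_s", min = 0, strict_min = TRUE)
  n_samp <- round(epoch_s * rec$fs)
  n_ep <- nrow(rec$data) %/% n_samp
  if (n_ep < 1) {
    stop_input(sprintf("recording (%.3g s) is shorter than one %g-s epoch",
                       rec_duration(rec), epoch_s))
  }
  discarded <- nrow(rec$data) - n_ep * n_samp
  if (discarded > 0) {
    inform(sprintf("segment_epochs: discarded %.3g s trailing remainder",
                   discarded / rec$fs))
  }
  n_ch <- ncol(rec$data)
  data <- array(0, c(n_samp, n_ep, n_ch))
  for (j in seq_len(n_ep)) {
    data[, j, ] <- rec$data[((j - 1) * n_samp + 1):(j * n_samp), ]
  }
  new_epoch_set(data, rec$fs, c(0, epoch_s), rec$channels)
}

#' Remove each epoch's median (offset correction)
#'
#' Per epoch and channel, the median over the whole epoch is subtracted from
#' every sample, so the per-epoch median is zero afterwards. Idempotent.
#'
#' @param es An `epoch_set`.
#' @return The offset-corrected `epoch_set`.
#' @export
offset_correct <- function(es) {
  stopifnot(inherits(es, "epoch_set"))
  med <- apply(es$data, c(2, 3), median)
  es$data <- es$data - rep(med, each = dim(es$data)[1])
  es$offset_corrected <- TRUE
  es
}

#' Reject epochs by absolute sample amplitude
#'
#' An epoch is rejected when the amplitude of any sample, on any channel
#' (or per channel with `per_channel = TRUE`), strictly exceeds
#' `+threshold` or falls strictly below `-threshold`; samples exactly at the
#' threshold are retained ("exceeds" is read as strict). Intended to run
#' after [offset_correct()].
#'
#' @param es An `epoch_set`.
#' @param threshold_uv Rejection threshold, microvolts (default 300).
#' @param per_channel If `TRUE`, channels are screened independently and an
#'   epoch is rejected only for channels that exceed the threshold (the mask
#'   still drops the whole epoch; the conservative all-channel rule is the
#'   default).
#' @return The `epoch_set` with its rejection mask updated (reason
#'   `"amplitude"`). Already-rejected epochs stay rejected.
#' @export
reject_epochs_amplitude <- function(es, threshold_uv = 300, per_channel = FALSE) {
  stopifnot(inherits(es, "epoch_set"))
  check_number(threshold_uv, "threshold_uv", min = 0, strict_min = TRUE)
  peak <- apply(abs(es$data), 2, max) # max over samples and channels
  bad <- peak > threshold_uv
  es$reason[bad & !es$rejected] <- "amplitude"
  es$rejected <- es$rejected | bad
  if (n_retained(es) == 0) {
    warn("amplitude rule rejected every epoch; downstream analysis will fail")
  }
  es
}

#' Reject epochs by peak-to-peak amplitude
#'
#' An epoch is rejected when its peak-to-peak amplitude (max minus min) on
#' any channel is strictly higher than `threshold_uv` (default 400);
#' exactly-at-threshold epochs are retained.
#'
#' @param es An `epoch_set`.
#' @param threshold_uv Peak-to-peak threshold, microvolts.
#' @return The `epoch_set` with its rejection mask updated (reason `"p2p"`).
#' @export
reject_epochs_p2p <- function(es, threshold_uv = 400) {
  stopifnot(inherits(es, "epoch_set"))
  check_number(threshold_uv, "threshold_uv", min = 0, strict_min = TRUE)
  p2p <- apply(es$data, c(2, 3), function(v) max(v) - min(v))
  bad <- apply(p2p > threshold_uv, 1, any)
  es$reason[bad & !es$rejected] <- "p2p"
  es$rejected <- es$rejected | bad
  if (n_retained(es) == 0) {
    warn("peak-to-peak rule rejected every epoch; downstream analysis will fail")
  }
  es
}
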