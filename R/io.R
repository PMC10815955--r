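# Recording and event I/O. Columnar text goes through readr; EDF (European
# Data Format, 16-bit integers with per-signal physical scaling) is written
# and read directly with readBin/writeBin since the format's fixed-width
# ASCII header and little-endian payload need no external dependency.

#' Write / read a recording as columnar text
#'
#' Comma-separated, header row, `time_s` column plus one column per channel,
#' amplitudes in microvolts.
#'
#' @param rec An [eeg_recording()].
#' @param path File path.
#' @return `read_recording_csv()` returns an [eeg_recording()];
#'   `write_recording_csv()` returns `path` invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  readr::write_csv(as_tibble(rec), path)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  df <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  )
  if (!"time_s" %in% names(df)) {
    stop_parse("columnar recording must contain a 'time_s' column")
  }
  for (col in names(df)) {
    if (!is.numeric(df[[col]])) {
      num <- suppressWarnings(as.numeric(df[[col]]))
      bad_row <- which(is.na(num) & !is.na(df[[col]]))[1]
      stop_parse(sprintf(
        "non-numeric value in '%s', column '%s', data row %d",
        path, col, if (is.na(bad_row)) 1L else bad_row
      ))
    }
  }
  bad <- !complete.cases(df)
  if (any(bad)) {
    stop_parse(sprintf("missing value in '%s' at data row %d",
                       path, which(bad)[1]))
  }
  t <- df$time_s
  if (nrow(df) < 2) stop_parse("recording must contain >= 2 samples")
  dt <- diff(t)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1] + 1e-12) {
    stop_parse("time column is not uniformly sampled")
  }
  eeg_recording(as.matrix(df[setdiff(names(df), "time_s")]),
                fs = 1 / dt[1], start_time = t[1])
}

#' Write / read a stimulus-onset event series (CSV, `onset_s` column)
#'
#' @param events An [event_series()].
#' @param path File path.
#' @export
write_events_csv <- function(events, path) {
  readr::write_csv(tibble(onset_s = events$onset_s), path)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"onset_s" %in% names(df)) stop_parse("events file needs an 'onset_s' column")
  if (!is.numeric(df$onset_s)) stop_parse("'onset_s' must be numeric")
  event_series(df$onset_s)
}

# ---- EDF ----

edf_pad <- function(x, width) {
  x <- substr(format(x, scientific = FALSE, trim = TRUE), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to EDF
#'
#' European Data Format: 16-bit samples with per-signal physical (microvolt)
#' scaling. Record duration is 1 s (or the whole recording when shorter);
#' a trailing partial record is zero-padded and the true sample count stored
#' in the header's reserved field so the round trip is exact in length.
#'
#' @param rec An [eeg_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- length(rec$channels)
  n <- nrow(rec$data)
  rec_dur <- if (n >= rec$fs) 1 else n / rec$fs
  spr <- round(rec$fs * rec_dur) # samples per record per signal
  n_rec <- ceiling(n / spr)
  phys_max <- vapply(seq_len(ns), function(j) {
    m <- max(abs(rec$data[, j]), 1e-6)
    ceiling(m * 1.0001)
  }, numeric(1))

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80), # patient id
    edf_pad("Startdate X X X X", 80), # recording id
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(as.character(256 * (1 + ns)), 8),
    edf_pad(sprintf("n=%d", n), 44), # reserved: true per-signal sample count
    edf_pad(as.character(n_rec), 8),
    edf_pad(format(rec_dur, digits = 8), 8),
    edf_pad(as.character(ns), 4)
  )
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  fields <- list(
    list(rec$channels, 16),
    list(rep("EEG telemetry", ns), 80), # transducer
    list(rep("uV", ns), 8),
    list(-phys_max, 8), list(phys_max, 8),
    list(rep(-32768, ns), 8), list(rep(32767, ns), 8),
    list(rep("", ns), 80), # prefiltering
    list(rep(spr, ns), 8),
    list(rep("", ns), 32) # reserved
  )
  for (f in fields) {
    writeChar(paste0(edf_pad(f[[1]], f[[2]]), collapse = ""), con,
              eos = NULL, useBytes = TRUE)
  }
  gain <- (2 * phys_max) / 65535
  padded <- matrix(0, n_rec * spr, ns)
  padded[seq_len(n), ] <- rec$data
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * spr + 1):(r * spr)
    block <- vapply(seq_len(ns), function(j) {
      # inverse of the reader's phys = phys_min + (d - dig_min) * gain
      as.integer(round((padded[rows, j] + phys_max[j]) / gain[j])) - 32768L
    }, integer(spr))
    writeBin(as.integer(pmin(pmax(block, -32768L), 32767L)), con,
             size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' @param path EDF file path.
#' @return An [eeg_recording()] in physical units (microvolts).
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8) # version
  rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- suppressWarnings(as.integer(rd(8)))
  reserved <- rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (is.na(ns) || ns < 1) stop_parse("EDF header: invalid signal count")
  if (is.na(n_rec) || is.na(rec_dur) || rec_dur <= 0) {
    stop_parse("EDF header: invalid record count or duration")
  }
  if (!is.na(hdr_bytes) && hdr_bytes != 256 * (1 + ns)) {
    stop_parse("EDF header: header-size field inconsistent with signal count")
  }
  rd_vec <- function(w, numeric = FALSE) {
    v <- vapply(seq_len(ns), function(i) rd(w), character(1))
    if (numeric) suppressWarnings(as.numeric(v)) else v
  }
  labels <- rd_vec(16)
  rd_vec(80); rd_vec(8)
  phys_min <- rd_vec(8, TRUE); phys_max <- rd_vec(8, TRUE)
  dig_min <- rd_vec(8, TRUE); dig_max <- rd_vec(8, TRUE)
  rd_vec(80)
  spr <- rd_vec(8, TRUE)
  rd_vec(32)
  if (any(is.na(c(phys_min, phys_max, dig_min, dig_max, spr)))) {
    stop_parse("EDF header: non-numeric scaling field")
  }
  if (length(unique(spr)) != 1) {
    stop_parse("EDF signals with differing sampling rates are not supported")
  }
  spr <- spr[1]
  fs <- spr / rec_dur
  data <- matrix(0, n_rec * spr, ns)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = spr * ns, size = 2, signed = TRUE,
                   endian = "little")
    if (length(raw) < spr * ns) stop_parse("EDF payload truncated")
    data[((r - 1) * spr + 1):(r * spr), ] <- matrix(raw, spr, ns)
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (j in seq_len(ns)) {
    data[, j] <- phys_min[j] + (data[, j] - dig_min[j]) * gain[j]
  }
  n_true <- suppressWarnings(as.integer(sub("^n=", "", reserved)))
  if (!is.na(n_true) && n_true <= nrow(data)) data <- data[seq_len(n_true), , drop = FALSE]
  eeg_recording(data, fs, labels)
}
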