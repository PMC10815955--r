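# Quantitative EEG: Hanning periodogram per fixed-length epoch and summed
# band power. Spectra are one-sided with energy (sum(w^2)) normalization,
# P_k = 2|X_k|^2 / (N * sum(w^2)) (factor 1 at DC/Nyquist), which makes the
# spectrum satisfy Parseval (sum over bins ~ mean squared signal) and gives
# a bin-centered unit-amplitude sinusoid a TOTAL leaked band power of
# amplitude^2/2 regardless of the window.

hanning_window <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))

#' Hanning-windowed power spectra of fixed-length epochs
#'
#' Per retained epoch and channel: the epoch is multiplied by a Hanning
#' window, Fourier transformed, and the power obtained as the product of the
#' complex spectrum with its conjugate, scaled as described above. With 4-s
#' epochs the bin spacing is 0.25 Hz; the range always runs 0 to fs/2.
#'
#' @param es An `epoch_set` (typically from [segment_epochs()] after
#'   [reject_epochs_p2p()]).
#' @return An object of class `spectrum_set`: `power` array
#'   `[freq, epoch, channel]` in microvolts squared per bin, `freqs`, and
#'   `n_epochs_used`.
#' @export
power_spectrum <- function(es) {
  stopifnot(inherits(es, "epoch_set"))
  if (n_retained(es) == 0) stop_input("no retained epochs for spectral analysis")
  dat <- retained_data(es)
  n <- dim(dat)[1]
  w <- hanning_window(n)
  norm <- n * sum(w^2)
  n_bins <- n %/% 2 + 1
  power <- array(0, c(n_bins, dim(dat)[2], dim(dat)[3]))
  for (ch in seq_len(dim(dat)[3])) {
    m <- dat[, , ch, drop = FALSE]
    dim(m) <- dim(m)[1:2]
    x_f <- mvfft(m * w)[seq_len(n_bins), , drop = FALSE]
    p <- 2 * Re(x_f * Conj(x_f)) / norm
    p[1, ] <- p[1, ] / 2
    if (n %% 2 == 0) p[n_bins, ] <- p[n_bins, ] / 2
    power[, , ch] <- p
  }
  structure(
    list(
      power = power,
      freqs = (seq_len(n_bins) - 1) * es$fs / n,
      channels = es$channels, fs = es$fs,
      n_epochs_used = dim(dat)[2]
    ),
    class = "spectrum_set"
  )
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf(
    "<spectrum_set> %d epochs x %d channel(s); %d bins, %.3g-Hz resolution, 0-%g Hz\n",
    x$n_epochs_used, length(x$channels), length(x$freqs),
    x$freqs[2] - x$freqs[1], max(x$freqs)
  ))
  invisible(x)
}

#' @export
as_tibble.spectrum_set <- function(x, ...) {
  d <- dim(x$power)
  tibble(
    channel = rep(x$channels, each = d[1] * d[2]),
    epoch = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    freq_hz = rep(x$freqs, times = d[2] * d[3]),
    power = as.vector(x$power)
  )
}

#' Summed band power
#'
#' Sums spectrum values over all bins inside `band`, endpoints inclusive
#' (the 32-80 Hz gamma band by default). Returns both the per-epoch values
#' and the session value (mean over retained epochs).
#'
#' @param ss A `spectrum_set`.
#' @param band `(f_lo, f_hi)` in Hz, inside the spectrum range.
#' @return A list of tibbles: `epochs` (channel, epoch, power) and
#'   `session` (channel, band_power = mean over epochs, n_epochs).
#' @export
band_power <- function(ss, band = c(32, 80)) {
  stopifnot(inherits(ss, "spectrum_set"))
  if (length(band) != 2L || band[1] >= band[2]) {
    stop_config("`band` must be (f_lo, f_hi) with f_lo < f_hi")
  }
  if (band[1] < min(ss$freqs) - 1e-9 || band[2] > max(ss$freqs) + 1e-9) {
    stop_config(sprintf("band [%g, %g] Hz outside spectrum range [0, %g] Hz",
                        band[1], band[2], max(ss$freqs)))
  }
  sel <- ss$freqs >= band[1] - 1e-9 & ss$freqs <= band[2] + 1e-9
  if (!any(sel)) stop_config("band contains no frequency bins")
  d <- dim(ss$power)
  per_epoch <- apply(ss$power[sel, , , drop = FALSE], c(2, 3), sum)
  epochs <- tibble(
    channel = rep(ss$channels, each = d[2]),
    epoch = rep(seq_len(d[2]), times = d[3]),
    power = as.vector(per_epoch)
  )
  session <- dplyr::summarise(
    dplyr::group_by(epochs, .data$channel),
    band_power = mean(.data$power), n_epochs = dplyr::n(), .groups = "drop"
  )
  list(epochs = epochs, session = session, band = band)
}
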