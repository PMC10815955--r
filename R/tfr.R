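# Morlet time-frequency analysis and the phase-locking factor (inter-trial
# coherence). The wavelet is a complex exponential under a Gaussian envelope
# with total support n_cycles/f seconds (half-length n_cycles/(2f), e.g.
# 93.75 ms for 9 cycles at 48 Hz) and envelope sigma_t = support/7, so the
# envelope is essentially zero at the truncation points. Kernels are
# unit-energy normalized.

#' Complex Morlet wavelet kernel
#'
#' @param f Center frequency, Hz (must be below fs/2).
#' @param fs Sampling rate, Hz.
#' @param n_cycles Number of cycles in the wavelet support (default 9).
#' @return Complex vector of odd length with attributes `half_length_s`
#'   (the half support, `n_cycles / (2 f)` seconds) and `f`.
#' @examples
#' k <- morlet_kernel(48, fs = 1000)
#' attr(k, "half_length_s") # 0.09375 s
#' @export
morlet_kernel <- function(f, fs, n_cycles = 9) {
  check_number(f, "f", min = 0, strict_min = TRUE)
  check_number(n_cycles, "n_cycles", min = 1)
  if (f >= fs / 2) {
    stop_config(sprintf("wavelet frequency %g Hz is at/above Nyquist (fs/2 = %g)", f, fs / 2))
  }
  support <- n_cycles / f
  half_n <- floor(support / 2 * fs)
  t <- (-half_n:half_n) / fs
  sigma_t <- support / 7
  k <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma_t^2))
  k <- k / sqrt(sum(Mod(k)^2) / fs) # unit energy: sum |k|^2 dt = 1
  attr(k, "half_length_s") <- support / 2
  attr(k, "f") <- f
  k
}

# FFT convolution of an [n_samp x n_epoch] real matrix with each kernel;
# returns, per kernel, the center-aligned ("same") complex coefficients.
# One forward transform is shared across kernels.
convolve_epochs <- function(mat, kernels, fs) {
  n_samp <- nrow(mat)
  lens <- vapply(kernels, length, integer(1))
  nfft <- nextn(n_samp + max(lens) - 1, 2)
  pad <- rbind(mat, matrix(0, nfft - n_samp, ncol(mat)))
  f_mat <- mvfft(pad)
  lapply(seq_along(kernels), function(i) {
    k <- kernels[[i]]
    kf <- fft(c(k, complex(real = rep(0, nfft - lens[i]))))
    cc <- mvfft(f_mat * kf, inverse = TRUE) / nfft
    half <- (lens[i] - 1L) / 2L
    cc[(half + 1L):(half + n_samp), , drop = FALSE]
  })
}

tfr_valid_mask <- function(n_samp, kernels) {
  vapply(kernels, function(k) {
    half <- (length(k) - 1L) / 2L
    v <- rep(FALSE, n_samp)
    if (n_samp > 2 * half) v[(half + 1L):(n_samp - half)] <- TRUE
    v
  }, logical(n_samp))
}

#' Per-epoch Morlet time-frequency transform
#'
#' Convolves every retained epoch of an `epoch_set` with Morlet kernels at
#' the requested analysis frequencies (default 48-52 Hz in 0.5-Hz steps, the
#' gamma box around a 50-Hz steady-state response). Edge samples where the
#' kernel overhangs the epoch are flagged invalid and excluded from all
#' downstream region averages.
#'
#' @param es An `epoch_set` with at least one retained epoch.
#' @param freqs Analysis frequencies, Hz.
#' @param n_cycles Wavelet cycles (default 9).
#' @return An object of class `epoch_tfr`: complex coefficients
#'   `[time, freq, epoch, channel]` plus the validity mask. For large epoch
#'   counts prefer calling [plf()] directly on the `epoch_set`, which
#'   accumulates across epochs in blocks without materializing this array.
#' @export
epoch_tfr <- function(es, freqs = seq(48, 52, by = 0.5), n_cycles = 9) {
  stopifnot(inherits(es, "epoch_set"))
  if (n_retained(es) == 0) stop_input("no retained epochs to transform")
  kernels <- lapply(freqs, morlet_kernel, fs = es$fs, n_cycles = n_cycles)
  dat <- retained_data(es)
  dims <- dim(dat)
  coef <- array(complex(1), c(dims[1], length(freqs), dims[2], dims[3]))
  for (ch in seq_len(dims[3])) {
    m <- dat[, , ch, drop = FALSE]
    dim(m) <- dim(m)[1:2]
    cc <- convolve_epochs(m, kernels, es$fs)
    for (i in seq_along(freqs)) coef[, i, , ch] <- cc[[i]]
  }
  structure(
    list(
      coef = coef, times = es$times, freqs = freqs, channels = es$channels,
      fs = es$fs, n_cycles = n_cycles,
      valid = tfr_valid_mask(dims[1], kernels),
      n_epochs_used = dims[2]
    ),
    class = "epoch_tfr"
  )
}

new_plf_map <- function(values, times, freqs, channels, valid, n_epochs_used) {
  values[rep(!valid, times = dim(values)[3])] <- NA_real_
  structure(
    list(values = values, times = times, freqs = freqs, channels = channels,
         valid = valid, n_epochs_used = n_epochs_used),
    class = "plf_map"
  )
}

#' @export
print.plf_map <- function(x, ...) {
  cat(sprintf(
    "<plf_map> %d times x %d freqs (%g-%g Hz) x %d channel(s), %d epochs used; PLF range [%.3f, %.3f]\n",
    length(x$times), length(x$freqs), min(x$freqs), max(x$freqs),
    length(x$channels), x$n_epochs_used,
    min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)
  ))
  invisible(x)
}

#' @export
as_tibble.plf_map <- function(x, ...) {
  tibble(
    channel = rep(x$channels, each = length(x$times) * length(x$freqs)),
    time_s = rep(x$times, times = length(x$freqs) * length(x$channels)),
    freq_hz = rep(rep(x$freqs, each = length(x$times)), times = length(x$channels)),
    plf = as.vector(x$values)
  )
}

#' Phase-locking factor (inter-trial coherence)
#'
#' Each epoch's complex coefficient is divided by its magnitude (unit
#' phasor; zero-magnitude cells are excluded), the phasors are averaged
#' across epochs, and the magnitude of the average is taken, giving a value
#' in `[0, 1]` per (time, frequency, channel) cell: 1 for perfect phase
#' consistency, tending to the Rayleigh floor
#' [rayleigh_plf_expectation()] for uniform phases. Amplitude information is
#' discarded entirely, so the statistic is invariant to per-epoch rescaling.
#'
#' @param x An `epoch_tfr`, or an `epoch_set` (coefficients are then computed
#'   block-wise and accumulated, which is the memory-safe path for
#'   1500-trial sessions).
#' @param ... Passed on to [epoch_tfr()] machinery (`freqs`, `n_cycles`,
#'   `block` for the epoch-set method).
#' @return A `plf_map`.
#' @export
plf <- function(x, ...) UseMethod("plf")

#' @rdname plf
#' @export
plf.epoch_tfr <- function(x, ...) {
  n_ep <- dim(x$coef)[3]
  if (n_ep < 2) stop_input("PLF needs >= 2 retained epochs")
  mag <- Mod(x$coef)
  unit <- x$coef
  nz <- mag > 0
  unit[nz] <- unit[nz] / mag[nz]
  unit[!nz] <- 0
  acc <- apply(unit, c(1, 2, 4), sum)
  cnt <- apply(nz, c(1, 2, 4), sum)
  vals <- Mod(acc) / pmax(cnt, 1)
  vals[cnt == 0] <- NA_real_
  new_plf_map(vals, x$times, x$freqs, x$channels, x$valid, n_ep)
}

#' @rdname plf
#' @param freqs Analysis frequencies, Hz.
#' @param n_cycles Wavelet cycles.
#' @param block Epochs per accumulation block.
#' @export
plf.epoch_set <- function(x, freqs = seq(48, 52, by = 0.5), n_cycles = 9,
                          block = 192, ...) {
  if (n_retained(x) < 2) stop_input("PLF needs >= 2 retained epochs")
  kernels <- lapply(freqs, morlet_kernel, fs = x$fs, n_cycles = n_cycles)
  dat <- retained_data(x)
  dims <- dim(dat)
  n_t <- dims[1]; n_f <- length(freqs); n_ch <- dims[3]
  acc <- array(complex(1), c(n_t, n_f, n_ch))
  cnt <- array(0, c(n_t, n_f, n_ch))
  starts <- seq(1, dims[2], by = block)
  for (s in starts) {
    idx <- s:min(s + block - 1, dims[2])
    for (ch in seq_len(n_ch)) {
      m <- dat[, idx, ch, drop = FALSE]
      dim(m) <- dim(m)[1:2]
      cc <- convolve_epochs(m, kernels, x$fs)
      for (i in seq_len(n_f)) {
        m <- Mod(cc[[i]])
        nz <- m > 0
        u <- cc[[i]]
        u[nz] <- u[nz] / m[nz]
        u[!nz] <- 0
        acc[, i, ch] <- acc[, i, ch] + rowSums(u)
        cnt[, i, ch] <- cnt[, i, ch] + rowSums(nz)
      }
    }
  }
  vals <- Mod(acc) / pmax(cnt, 1)
  vals[cnt == 0] <- NA_real_
  new_plf_map(vals, x$times, freqs, x$channels,
              tfr_valid_mask(n_t, kernels), dims[2])
}

#' ROI-minus-baseline PLF contrast
#'
#' Scalar per-channel endpoint of the steady-state analysis: the mean PLF
#' over the post-stimulus region of interest minus the mean over the
#' pre-stimulus baseline. Both windows are shortened by `trim_s` at both
#' ends (default 0.100 s, the 9-cycle/48-Hz wavelet half-length 93.75 ms
#' rounded up) to protect the region means from edge and stimulus-transition
#' smearing; cells flagged invalid by kernel overhang are excluded as well.
#' Regions are averaged over the full (time x frequency) box after epoch
#' averaging.
#'
#' @param map A `plf_map`.
#' @param bl_window Baseline window, seconds relative to onset.
#' @param roi_window Post-stimulus window, seconds.
#' @param trim_s Seconds trimmed from both ends of both windows.
#' @return A tibble (channel, bl, roi, contrast) with the effective windows
#'   as attributes; `contrast` lies in `[-1, 1]`.
#' @export
plf_contrast <- function(map, bl_window = c(-0.5, 0), roi_window = c(0, 0.5),
                         trim_s = 0.1) {
  stopifnot(inherits(map, "plf_map"))
  check_number(trim_s, "trim_s", min = 0)
  window_mean <- function(w) {
    lo <- w[1] + trim_s
    hi <- w[2] - trim_s
    if (hi <= lo) {
      stop_config(sprintf("trim %g s leaves window [%g, %g] empty", trim_s, w[1], w[2]))
    }
    sel <- map$times >= lo - 1e-9 & map$times <= hi + 1e-9
    if (!any(sel)) stop_config("trimmed window contains no time samples")
    vapply(seq_along(map$channels), function(ch) {
      mean(map$values[sel, , ch], na.rm = TRUE)
    }, numeric(1))
  }
  bl <- window_mean(bl_window)
  roi <- window_mean(roi_window)
  if (any(!is.finite(bl)) || any(!is.finite(roi))) {
    stop_config("contrast windows contain no valid (non-edge) PLF cells")
  }
  out <- tibble(channel = map$channels, bl = bl, roi = roi, contrast = roi - bl)
  attr(out, "bl_window_eff") <- c(bl_window[1] + trim_s, bl_window[2] - trim_s)
  attr(out, "roi_window_eff") <- c(roi_window[1] + trim_s, roi_window[2] - trim_s)
  attr(out, "n_epochs_used") <- map$n_epochs_used
  out
}

#' Percent-of-reference normalization
#'
#' Divides each subject's endpoint by the reference-arm mean and multiplies
#' by 100, the reporting convention for treated-vs-vehicle comparisons
#' (e.g. a drug arm "at 40% of the vehicle-treated group"). If the reference
#' mean is not positive the normalization is flagged and raw values are
#' returned in `percent` unchanged, with a warning.
#'
#' @param data Tibble with one row per subject.
#' @param value Name of the endpoint column.
#' @param reference Reference arm label.
#' @param arm Name of the arm column.
#' @return `data` with a `percent` column appended (attribute `normalized`
#'   says whether normalization succeeded).
#' @export
percent_of_reference <- function(data, value = "value", reference,
                                 arm = "arm") {
  vals <- data[[value]]
  arms <- data[[arm]]
  if (!reference %in% arms) {
    stop_config(sprintf("reference arm '%s' absent from data", reference))
  }
  ref_mean <- mean(vals[arms == reference])
  if (!is.finite(ref_mean) || ref_mean <= 0) {
    warn("reference-arm mean is not positive; reporting raw values instead of percentages")
    data$percent <- vals
    attr(data, "normalized") <- FALSE
    return(data)
  }
  data$percent <- 100 * vals / ref_mean
  attr(data, "normalized") <- TRUE
  data
}
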