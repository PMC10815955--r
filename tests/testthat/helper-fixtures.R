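# Fixture builders shared across test files. Everything is generated in code
# at test time; nothing is read from disk except files the tests write first.

# Epoch set of pure sinusoids with one phase per epoch (optionally plus white
# noise): the minimal signal with an analytic PLF.
sine_epochs <- function(phases, fs = 500, window = c(-0.5, 1), f = 50,
                        amplitude = 20, noise_sd = 0, active = NULL,
                        seed = NULL) {
  n_samp <- round((window[2] - window[1]) * fs)
  times <- window[1] + (seq_len(n_samp) - 1) / fs
  on <- if (is.null(active)) rep(TRUE, n_samp) else (times >= active[1] & times < active[2])
  make <- function() {
    dat <- vapply(phases, function(ph) {
      x <- numeric(n_samp)
      x[on] <- amplitude * cos(2 * pi * f * times[on] + ph)
      if (noise_sd > 0) x <- x + rnorm(n_samp, sd = noise_sd)
      x
    }, numeric(n_samp))
    epoch_set(array(dat, c(n_samp, length(phases), 1)), fs, window, "ch1")
  }
  if (is.null(seed)) make() else withr::with_seed(seed, make())
}

# PLF at the cell nearest (time, freq).
plf_at <- function(map, time, freq) {
  map$values[which.min(abs(map$times - time)), which.min(abs(map$freqs - freq)), 1]
}

# Tiny deterministic activity table: one subject per arm unless told otherwise.
toy_activity <- function(counts_by_subject, bin_min = 10) {
  purrr::imap_dfr(counts_by_subject, function(counts, subj) {
    tibble::tibble(
      subject = subj, arm = sub("_.*", "", subj),
      bin = seq_along(counts),
      t0_min = (seq_along(counts) - 1) * bin_min,
      t1_min = seq_along(counts) * bin_min,
      counts = as.integer(counts)
    )
  })
}
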