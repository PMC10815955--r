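# Morlet kernel contracts, TFR linearity/eigenfunction behavior, and the
# PLF's closed-form targets: Bessel-ratio recovery and the Rayleigh floor.

test_that("9-cycle kernel at 48 Hz has half-length 93.75 ms and unit energy", {
  fs <- 1000
  k <- morlet_kernel(48, fs)
  expect_equal(attr(k, "half_length_s"), 0.09375) # prints as 94 ms
  expect_equal(round(attr(k, "half_length_s") * 1000), 94)
  expect_equal(length(k) %% 2, 1)
  expect_equal(sum(Mod(k)^2) / fs, 1)
  # spectral peak sits at the nominal frequency
  nfft <- 8192
  spec <- Mod(fft(c(k, rep(0, nfft - length(k)))))^2
  f_grid <- (seq_len(nfft) - 1) * fs / nfft
  expect_lt(abs(f_grid[which.max(spec[1:(nfft / 2)])] - 48), 1)
  expect_error(morlet_kernel(300, fs = 500), class = "gammassr_config_error")
})

test_that("TFR magnitude is flat on a pure tone and scales linearly", {
  es1 <- sine_epochs(0, amplitude = 10)
  es2 <- sine_epochs(0, amplitude = 20)
  tf1 <- epoch_tfr(es1, freqs = 50)
  tf2 <- epoch_tfr(es2, freqs = 50)
  interior <- tf1$valid[, 1]
  m1 <- Mod(tf1$coef[interior, 1, 1, 1])
  expect_lt(diff(range(m1)) / mean(m1), 1e-3)
  expect_equal(Mod(tf2$coef[interior, 1, 1, 1]) / m1, rep(2, sum(interior)),
               tolerance = 1e-9)
})

test_that("TFR ridge tracks the instantaneous frequency of a chirp", {
  fs <- 1000
  window <- c(-0.5, 1)
  times <- window[1] + (seq_len(1500) - 1) / fs
  # linear chirp 46 -> 54 Hz across the epoch: f_inst(t) = 50 + 16/3 * t
  f0 <- 50; rate <- 8 / 1.5
  x <- cos(2 * pi * (f0 * times + rate * times^2 / 2))
  es <- epoch_set(array(x, c(1500, 1, 1)), fs, window)
  tf <- epoch_tfr(es, freqs = seq(46, 54, by = 0.5))
  for (t_probe in c(-0.2, 0, 0.2)) {
    i <- which.min(abs(tf$times - t_probe))
    ridge <- tf$freqs[which.max(Mod(tf$coef[i, , 1, 1]))]
    expect_lt(abs(ridge - (f0 + rate * t_probe)), 0.75)
  }
})

test_that("identical epochs give PLF exactly 1 at every valid cell", {
  one <- withr::with_seed(3, rnorm(750, sd = 12))
  es <- epoch_set(array(rep(one, 5), c(750, 5, 1)), 500, c(-0.5, 1))
  map <- plf(es)
  expect_equal(range(map$values, na.rm = TRUE), c(1, 1), tolerance = 1e-9)
})

test_that("PLF is invariant to per-epoch amplitude rescaling and bounded", {
  for (seed in 1:3) {
    phases <- withr::with_seed(seed, runif(30, -pi, pi))
    es <- sine_epochs(phases, noise_sd = 5, seed = seed + 100)
    map1 <- plf(es)
    scales <- withr::with_seed(seed + 200, runif(30, 0.1, 10))
    es2 <- es
    es2$data <- es$data * rep(scales, each = dim(es$data)[1])
    map2 <- plf(es2)
    expect_equal(map1$values, map2$values, tolerance = 1e-9)
    rng <- range(map1$values, na.rm = TRUE)
    expect_gte(rng[1], 0)
    expect_lte(rng[2], 1)
  }
})

test_that("uniform-phase PLF concentrates at the Rayleigh expectation", {
  # short epochs keep this cheap: one valid probe cell is enough
  reps <- 24
  for (n_ep in c(8, 100, 1500)) {
    vals <- vapply(seq_len(reps), function(r) {
      phases <- withr::with_seed(1000 * n_ep + r, runif(n_ep, -pi, pi))
      es <- sine_epochs(phases, fs = 500, window = c(0, 0.4))
      plf_at(plf(es), 0.2, 50)
    }, numeric(1))
    target <- rayleigh_plf_expectation(n_ep)
    sd_theory <- sqrt((4 - pi) / (4 * n_ep))
    expect_lt(abs(mean(vals) - target), 3 * sd_theory / sqrt(reps))
  }
})

test_that("estimated PLF recovers the Bessel ratio over a kappa grid", {
  n_ep <- 1500
  for (kappa in c(0.5, 1, 2, 4, 8)) {
    phases <- withr::with_seed(round(10 * kappa), rvonmises(n_ep, 0, kappa))
    es <- sine_epochs(phases, fs = 500, window = c(0, 0.4))
    est <- plf_at(plf(es), 0.2, 50)
    pop <- plf_population(kappa)
    expected <- sqrt(pop^2 + (1 - pop^2) / n_ep) # finite-N resultant bias
    mc_se <- sqrt((1 - pop^2) / n_ep)
    expect_lt(abs(est - expected), 3 * mc_se)
  }
})

test_that("PLF map bookkeeping: edges invalid, epoch count recorded", {
  es <- sine_epochs(rep(0, 4), fs = 500, window = c(-0.5, 1))
  map <- plf(es)
  expect_true(all(is.na(map$values[1, , 1]))) # kernel overhangs the edge
  expect_equal(map$n_epochs_used, 4)
  expect_error(plf(sine_epochs(0)), class = "gammassr_input_error")
  # streaming accumulation equals the in-memory path
  phases <- withr::with_seed(9, runif(25, -pi, pi))
  es2 <- sine_epochs(phases, noise_sd = 3, seed = 11)
  expect_equal(plf(es2, block = 7)$values, plf(epoch_tfr(es2))$values,
               tolerance = 1e-10)
})

test_that("contrast is zero when phase locking is identical pre/post", {
  es <- sine_epochs(withr::with_seed(2, rvonmises(40, 0, 3)))
  ct <- plf_contrast(plf(es))
  expect_equal(ct$contrast, 0, tolerance = 1e-9)
  expect_equal(attr(ct, "bl_window_eff"), c(-0.4, -0.1))
  expect_equal(attr(ct, "roi_window_eff"), c(0.1, 0.4))
  expect_error(plf_contrast(plf(es), trim_s = 0.25),
               class = "gammassr_config_error")
})

test_that("post-stimulus locking yields contrast ~ population PLF minus Rayleigh bias", {
  n_ep <- 400
  kappa <- 4
  phases <- withr::with_seed(6, rvonmises(n_ep, 0, kappa))
  es <- sine_epochs(phases, fs = 500, amplitude = 30, noise_sd = 1,
                    active = c(0, 0.5), seed = 13)
  ct <- plf_contrast(plf(es))
  expected <- plf_population(kappa) - rayleigh_plf_expectation(n_ep)
  expect_equal(ct$contrast, expected, tolerance = 0.04)
  expect_gt(ct$roi, 0.8)
  expect_lt(ct$bl, 0.12)
})

test_that("contrast of a stationary process is centred on zero", {
  deltas <- vapply(1:12, function(r) {
    es <- sine_epochs(withr::with_seed(r, runif(60, -pi, pi)),
                      noise_sd = 10, amplitude = 0, seed = 300 + r)
    plf_contrast(plf(es))$contrast
  }, numeric(1))
  expect_lt(abs(mean(deltas)), 3 * sd(deltas) / sqrt(length(deltas)))
})

test_that("percent-of-reference normalization follows the reporting convention", {
  df <- tibble::tibble(
    arm = c("veh", "veh", "drug"),
    value = c(0.2, 0.2, 0.08)
  )
  out <- percent_of_reference(df, "value", reference = "veh")
  expect_equal(out$percent, c(100, 100, 40))
  expect_true(attr(out, "normalized"))
  df$value <- c(-1, -1, 2)
  expect_warning(raw <- percent_of_reference(df, "value", reference = "veh"))
  expect_false(attr(raw, "normalized"))
  expect_equal(raw$percent, df$value)
  expect_error(percent_of_reference(df, "value", reference = "nope"),
               class = "gammassr_config_error")
})
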