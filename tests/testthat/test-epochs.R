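# Epoch extraction, offset correction and the two amplitude-rejection rules,
# checked against index-arithmetic and direct-median oracles.

ramp_recording <- function(n = 6000, fs = 1000, n_ch = 2) {
  eeg_recording(matrix(seq_len(n * n_ch), n, n_ch), fs,
                paste0("ch", seq_len(n_ch)))
}

test_that("a full session splits into 1.5-s epochs of 1500 samples at 1 kHz", {
  sess <- simulate_assr_session(
    stim_protocol(), evoked_model(amplitude_uv = 0),
    background_model(pink_scale_uv = 0, gamma_scale = 0,
                     artifact_rate_per_min = 0),
    fs = 1000, channels = "ch1", seed = 1
  )
  es <- extract_epochs(sess$recording, sess$events)
  expect_equal(n_epochs(es), 1500)
  expect_equal(dim(es$data)[1], 1500)
  expect_equal(es$times[1], -0.5)
})

test_that("epoch content equals the known slice of a ramp signal", {
  rec <- ramp_recording()
  ev <- event_series(c(1.0, 2.5))
  es <- extract_epochs(rec, ev, window = c(-0.5, 1.0))
  # onset 1.0 s, t_min -0.5 s -> starts at sample index 501
  expect_equal(es$data[, 1, 1], as.numeric(501:2000))
  expect_equal(es$data[, 2, 2], as.numeric(6000 + 2001:3500))
  # relative time 0 maps to the onset sample
  expect_equal(es$data[which(abs(es$times) < 1e-12), 1, 1], 1001)
})

test_that("events whose window leaves the recording are dropped and counted", {
  rec <- ramp_recording(3000)
  expect_message(
    es <- extract_epochs(rec, event_series(c(0.2, 1.0, 2.9)),
                         window = c(-0.5, 1.0)),
    "dropped 2"
  )
  expect_equal(n_epochs(es), 1)
  expect_equal(es$n_dropped_events, 2L)
  expect_error(
    suppressMessages(
      extract_epochs(rec, event_series(0.1), window = c(-0.5, 1.0))
    ),
    class = "gammassr_input_error"
  )
})

test_that("epoch extraction is translation-equivariant", {
  rec <- make_noise_rec <- simulate_spontaneous(
    background_model(artifact_rate_per_min = 0), duration_s = 8, fs = 500,
    channels = "ch1", seed = 77
  )
  onsets <- c(1.0, 3.0, 5.5)
  es1 <- extract_epochs(rec, event_series(onsets))
  shifted <- eeg_recording(rec$data, rec$fs, rec$channels, start_time = 2.25)
  es2 <- extract_epochs(shifted, event_series(onsets + 2.25))
  expect_identical(es1$data, es2$data)
})

test_that("offset correction removes the epoch median and is idempotent", {
  # constant epochs collapse to zero
  dat <- array(42, c(10, 3, 2))
  es <- offset_correct(epoch_set(dat, 10, c(0, 1)))
  expect_true(all(es$data == 0))

  # direct-median oracle on an asymmetric pattern
  v <- c(1, 2, 3, 4, 100)
  es2 <- offset_correct(epoch_set(array(v, c(5, 1, 1)), 5, c(0, 1)))
  expect_equal(es2$data[, 1, 1], v - 3)

  # per-epoch/channel medians vanish on arbitrary data; second pass is a no-op
  dat3 <- array(withr::with_seed(1, rnorm(7 * 4 * 2, mean = 50)), c(7, 4, 2))
  es3 <- offset_correct(epoch_set(dat3, 7, c(0, 1)))
  expect_lt(max(abs(apply(es3$data, c(2, 3), median))), 1e-12)
  expect_equal(offset_correct(es3)$data, es3$data)

  # commutes with epoch-wise constant shifts
  shift <- array(rep(c(5, -3, 11, 0), each = 7), c(7, 4, 1))
  a <- offset_correct(epoch_set(dat3[, , 1, drop = FALSE] + shift, 7, c(0, 1)))
  b <- offset_correct(epoch_set(dat3[, , 1, drop = FALSE], 7, c(0, 1)))
  expect_equal(a$data, b$data)
})

test_that("sample-amplitude rejection is strict at +/-300 uV", {
  base <- array(0, c(100, 3, 1))
  base[50, 1, 1] <- 301   # strictly exceeds
  base[60, 2, 1] <- 300   # exactly at threshold: retained
  base[70, 3, 1] <- -301  # negative side
  es <- reject_epochs_amplitude(epoch_set(base, 100, c(0, 1)))
  expect_identical(es$rejected, c(TRUE, FALSE, TRUE))
  expect_identical(es$reason, c("amplitude", NA, "amplitude"))
})

test_that("an epoch bad on either channel is dropped for both", {
  dat <- array(0, c(50, 2, 2))
  dat[10, 1, 2] <- 400 # epoch 1 exceeds only on channel 2
  es <- reject_epochs_amplitude(epoch_set(dat, 50, c(0, 1)))
  expect_identical(es$rejected, c(TRUE, FALSE))
  expect_equal(dim(retained_data(es))[3], 2)
})

test_that("planted super-threshold artifacts are rejected one-for-one", {
  n_ep <- 30
  dat <- array(withr::with_seed(5, rnorm(200 * n_ep, sd = 10)), c(200, n_ep, 1))
  planted <- c(3, 11, 25)
  for (j in planted) dat[17, j, 1] <- 900
  es <- reject_epochs_amplitude(offset_correct(epoch_set(dat, 100, c(0, 2))))
  expect_identical(which(es$rejected), as.integer(planted))

  esp <- reject_epochs_p2p(epoch_set(dat, 100, c(0, 2)), threshold_uv = 400)
  expect_identical(which(esp$rejected), as.integer(planted))
})

test_that("rejection is monotone in the threshold", {
  dat <- array(withr::with_seed(6, rnorm(100 * 40, sd = 120)), c(100, 40, 1))
  es <- epoch_set(dat, 100, c(0, 1))
  n_prev <- Inf
  for (thr in c(100, 200, 300, 400)) {
    n_rej <- sum(suppressWarnings(
      reject_epochs_amplitude(es, threshold_uv = thr)
    )$rejected)
    expect_lte(n_rej, n_prev)
    n_prev <- n_rej
  }
})

test_that("peak-to-peak rejection is strict above 400 uV", {
  dat <- array(0, c(100, 3, 1))
  dat[1, 1, 1] <- -150; dat[2, 1, 1] <- 251 # p2p 401: rejected
  dat[1, 2, 1] <- -200; dat[2, 2, 1] <- 200 # p2p exactly 400: retained
  es <- reject_epochs_p2p(epoch_set(dat, 100, c(0, 1)))
  expect_identical(es$rejected, c(TRUE, FALSE, FALSE))
})

test_that("fixed segmentation floors to whole epochs and logs the remainder", {
  rec <- eeg_recording(matrix(rnorm(3950), ncol = 1), fs = 500)
  expect_message(es <- segment_epochs(rec, 4), "discarded")
  expect_equal(n_epochs(es), 1)
  # 3600-s scale check, shrunk: 360 s -> 90 four-second epochs
  rec2 <- eeg_recording(matrix(0, 360 * 100, 1), fs = 100)
  expect_equal(n_epochs(segment_epochs(rec2, 4)), 90)
  # boundaries at exact multiples of 4 s
  rec3 <- eeg_recording(matrix(seq_len(1200), ncol = 1), fs = 100)
  es3 <- segment_epochs(rec3, 4)
  expect_equal(es3$data[1, , 1], c(1, 401, 801))
  expect_error(segment_epochs(eeg_recording(matrix(0, 10, 1), 100), 4),
               class = "gammassr_input_error")
})
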