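# The generator must reproduce the study conditions (stimulus arithmetic)
# and its own closed-form expectations (von Mises resultant, 1/f slope,
# amplitude-squared band power, negative-binomial moments).

quiet_protocol <- function(n = 1500) {
  list(
    protocol = stim_protocol(n_stimuli = n),
    evoked = evoked_model(amplitude_uv = 0),
    background = background_model(pink_scale_uv = 0, gamma_scale = 0,
                                  artifact_rate_per_min = 0)
  )
}

test_that("default protocol produces 1500 onsets at cycle spacing over 30 min", {
  q <- quiet_protocol()
  sess <- simulate_assr_session(q$protocol, q$evoked, q$background,
                                fs = 200, seed = 1)
  expect_equal(nrow(sess$events), 1500)
  expect_equal(unique(round(diff(sess$events$onset_s), 9)), 1.2)
  expect_equal(diff(range(sess$events$onset_s)), 1499 * 1.2)
  # 1500 x 1.2-s cycles = 1800 s of stimulation, plus 1-s margins
  expect_equal(rec_duration(sess$recording), 1802)
  # null generator: no evoked, no background, no artifacts
  expect_true(all(sess$recording$data == 0))
})

test_that("identical inputs and seed reproduce bit-identical output", {
  p <- stim_protocol(n_stimuli = 20)
  e <- evoked_model(kappa = 2)
  b <- background_model()
  s1 <- simulate_assr_session(p, e, b, fs = 400, seed = 42)
  s2 <- simulate_assr_session(p, e, b, fs = 400, seed = 42)
  s3 <- simulate_assr_session(p, e, b, fs = 400, seed = 43)
  expect_identical(s1$recording$data, s2$recording$data)
  expect_identical(s1$events, s2$events)
  expect_false(identical(s1$recording$data, s3$recording$data))

  r1 <- simulate_spontaneous(b, duration_s = 10, fs = 400, seed = 7)
  r2 <- simulate_spontaneous(b, duration_s = 10, fs = 400, seed = 7)
  expect_identical(r1$data, r2$data)

  d <- default_assr_study(seed = 3, n_per_arm = 2)
  expect_identical(simulate_behavior(d), simulate_behavior(d))
  expect_identical(draw_subject_params(d), draw_subject_params(d))
})

test_that("trial-phase resultant matches the Bessel ratio I1(k)/I0(k)", {
  n <- 1500
  for (kappa in c(0, 4)) {
    target <- plf_population(kappa)
    ph <- withr::with_seed(11 + kappa, rvonmises(n, 0, kappa))
    r_hat <- Mod(mean(exp(1i * ph)))
    # expected estimate includes the finite-sample resultant bias
    expected <- sqrt(target^2 + (1 - target^2) / n)
    mc_se <- sqrt((1 - target^2) / n)
    expect_lt(abs(r_hat - expected), 3 * mc_se + 1e-12)
  }
  expect_equal(plf_population(4), 0.8635, tolerance = 1e-4)
  expect_equal(plf_population(2), 0.6978, tolerance = 1e-4)
  # kappa = 0 gives uniform phases over the full circle
  ph0 <- withr::with_seed(2, rvonmises(5000, 0, 0))
  expect_gt(max(ph0), 3)
  expect_lt(min(ph0), -3)
})

test_that("spontaneous recording has the requested length and 1/f slope", {
  bg <- background_model(pink_exponent = 1, pink_scale_uv = 10,
                         gamma_scale = 0, artifact_rate_per_min = 0)
  rec <- simulate_spontaneous(bg, duration_s = 20, fs = 1000, seed = 5)
  expect_equal(nrow(rec$data), 20000)
  expect_equal(length(rec$channels), 2)

  long <- simulate_spontaneous(bg, duration_s = 400, fs = 500,
                               channels = "ch1", seed = 6)
  ss <- power_spectrum(segment_epochs(long, 4))
  pw <- rowMeans(ss$power[, , 1])
  sel <- ss$freqs >= 1 & ss$freqs <= 100
  slope <- unname(coef(lm(log(pw[sel]) ~ log(ss$freqs[sel])))[2])
  expect_equal(slope, -1, tolerance = 0.1)
})

test_that("doubling the gamma amplitude quadruples band power exactly", {
  mk <- function(g) {
    simulate_spontaneous(
      background_model(pink_scale_uv = 0, gamma_scale = g,
                       artifact_rate_per_min = 0),
      duration_s = 40, fs = 500, channels = "ch1", seed = 9
    )
  }
  bp <- function(rec) {
    band_power(power_spectrum(segment_epochs(rec, 4)))$session$band_power
  }
  expect_equal(bp(mk(10)) / bp(mk(5)), 4, tolerance = 1e-9)
})

test_that("behavioral tables match their distributional moments and bounds", {
  arm_many <- study_arm(
    "veh", n_subjects = 200,
    behavior = behavior_model(activity_mean_profile = rep(10, 9),
                              activity_dispersion = 0.4)
  )
  des <- study_design(list(arm_many,
                           study_arm("drug", 2)), "veh", seed = 21)
  beh <- simulate_behavior(des)
  totals <- activity_sum(dplyr::filter(beh$activity, arm == "veh"),
                         window = c(0, 90))
  # NB moments: per-bin var = mu + disp * mu^2 = 50, total var = 450
  se <- sqrt(9 * (10 + 0.4 * 100) / 200)
  expect_lt(abs(mean(totals$value) - 90), 3 * se)
  expect_true(all(beh$activity$counts >= 0))

  # degenerate social SD: every pair sits exactly at the mean
  des0 <- study_design(list(study_arm(
    "veh", 5, behavior = behavior_model(social_sd_s = 0, social_mean_s = 57)
  ), study_arm("drug", 2)), "veh", seed = 1)
  expect_true(all(simulate_behavior(des0)$social$social_s[1:5] == 57))

  # vehicle-calibrated social arm stays inside the 600-s test
  soc <- simulate_behavior(default_assr_study(seed = 8, n_per_arm = 10))$social
  expect_true(all(soc$social_s >= 0 & soc$social_s <= 600))
})

test_that("generator rejects inconsistent configurations", {
  q <- quiet_protocol(10)
  expect_error(
    simulate_assr_session(q$protocol, q$evoked, q$background, fs = 100),
    class = "gammassr_config_error"
  ) # below Nyquist for the 80-Hz band edge
  expect_error(
    simulate_assr_session(q$protocol, q$evoked, q$background, fs = 200,
                          duration_s = 5),
    class = "gammassr_config_error"
  )
  expect_error(simulate_spontaneous(background_model(), duration_s = 0),
               class = "gammassr_config_error")
  expect_error(background_model(pink_scale_uv = -1),
               class = "gammassr_config_error")
})
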