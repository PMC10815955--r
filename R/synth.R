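# Synthetic-data generator: continuous EEG with a von Mises phase-jittered
# steady-state component, 1/f + band-limited gamma background, Poisson-timed
# artifacts, and behavioral tables with known moments. Every draw is made
# under withr::with_seed so identical (inputs, seed) give identical output.

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler. `kappa = 0` returns uniform phases on
#' (-pi, pi].
#'
#' @param n Number of draws.
#' @param mu Mean direction, radians.
#' @param kappa Concentration, >= 0.
#' @return Numeric vector of angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  check_number(kappa, "kappa", min = 0)
  if (kappa < 1e-10) {
    return(runif(n, -pi, pi))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      u3 <- runif(1)
      out[i] <- sign(u3 - 0.5) * acos(f) + mu
      i <- i + 1L
    }
  }
  ((out + pi) %% (2 * pi)) - pi
}

# Unit-RMS 1/f^alpha noise via spectral synthesis (slope exact by construction).
pink_noise_unit <- function(n, fs, exponent) {
  white <- rnorm(n)
  if (exponent == 0) {
    return(white / max(sd(white), .Machine$double.eps))
  }
  x_f <- fft(white)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k) * fs / n
  w <- c(0, f[-1]^(-exponent / 2)) # zero out DC
  x <- Re(fft(x_f * w, inverse = TRUE)) / n
  x / max(sd(x), .Machine$double.eps)
}

# Unit-RMS noise band-limited to `band` (brick-wall in the frequency domain).
band_noise_unit <- function(n, fs, band) {
  white <- rnorm(n)
  x_f <- fft(white)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k) * fs / n
  w <- as.numeric(f >= band[1] & f <= band[2])
  x <- Re(fft(x_f * w, inverse = TRUE)) / n
  x / max(sd(x), .Machine$double.eps)
}

# Biphasic 200-ms transient: one positive then one negative 100-ms lobe,
# peak +/- amplitude (peak-to-peak = 2 * amplitude).
artifact_waveform <- function(fs, amplitude_uv, duration_s = 0.2) {
  m <- max(2L, round(duration_s * fs))
  amplitude_uv * sin(2 * pi * (seq_len(m) - 1) / m)
}

# One channel of background activity; draw order fixed (pink, gamma,
# artifact count, artifact times) so that rescaling one component's
# amplitude leaves the other components' realizations unchanged.
background_channel <- function(n, fs, bg) {
  x <- bg$pink_scale_uv * pink_noise_unit(n, fs, bg$pink_exponent)
  x <- x + bg$gamma_scale * band_noise_unit(n, fs, bg$gamma_band)
  n_art <- rpois(1, bg$artifact_rate_per_min * (n / fs) / 60)
  if (n_art > 0) {
    wf <- artifact_waveform(fs, bg$artifact_amplitude_uv)
    starts <- sort(round(runif(n_art, 0, max(0, n - length(wf)))))
    for (s in starts) {
      idx <- (s + 1):(s + length(wf))
      x[idx] <- x[idx] + wf
    }
    attr(x, "artifact_onsets_s") <- starts / fs
  }
  x
}

#' Simulate an ASSR stimulation session
#'
#' Generates a continuous recording of `n_stimuli` click-train cycles plus
#' leading and trailing margins, together with the stimulus-onset event
#' series. The signal is the sum of 1/f background, band-limited gamma
#' background, Poisson-timed artifacts and, on each trial, a sinusoid at the
#' evoked carrier frequency active on
#' `[onset + latency, onset + latency + response_s)` whose phase is drawn
#' von Mises(0, kappa) once per trial (shared across channels, as both
#' cortical sites entrain to the same stimulus; background noise is
#' independent per channel).
#'
#' @param protocol A [stim_protocol()].
#' @param evoked An [evoked_model()].
#' @param background A [background_model()].
#' @param fs Sampling rate, Hz; must be at least twice the highest simulated
#'   frequency component.
#' @param channels Channel labels (one independent background per channel).
#' @param seed Integer seed.
#' @param duration_s Optional total recording duration; must be at least the
#'   protocol's span plus margins.
#' @return A list with elements `recording` ([eeg_recording()]) and
#'   `events` ([event_series()]).
#' @examples
#' sess <- simulate_assr_session(
#'   stim_protocol(n_stimuli = 5),
#'   evoked_model(kappa = 4), background_model(),
#'   fs = 500, seed = 1
#' )
#' nrow(sess$events)
#' @export
simulate_assr_session <- function(protocol, evoked, background, fs = 1000,
                                  channels = c("global_cortex", "auditory_cortex"),
                                  seed = 1L, duration_s = NULL) {
  stopifnot(inherits(protocol, "stim_protocol"), inherits(evoked, "evoked_model"),
            inherits(background, "background_model"))
  f_max <- max(evoked$carrier_freq, background$gamma_band[2])
  if (fs < 2 * f_max) {
    stop_config(sprintf(
      "fs = %g Hz is below the Nyquist rate for a %g-Hz component", fs, f_max
    ))
  }
  cycle <- protocol_cycle_s(protocol)
  if (evoked$onset_latency_s + evoked$response_s > cycle) {
    stop_config("evoked response extends past the stimulation cycle")
  }
  need_s <- protocol$start_offset_s * 2 + protocol$n_stimuli * cycle
  if (is.null(duration_s)) duration_s <- need_s
  if (duration_s < need_s) {
    stop_config(sprintf(
      "duration_s = %g s cannot hold %d stimuli of %g-s cycle plus margins (need %g s)",
      duration_s, protocol$n_stimuli, cycle, need_s
    ))
  }
  n <- round(duration_s * fs)
  onsets <- protocol$start_offset_s + (seq_len(protocol$n_stimuli) - 1) * cycle

  withr::with_seed(seed, {
    phases <- rvonmises(protocol$n_stimuli, 0, evoked$kappa)
    data <- matrix(0, n, length(channels))
    artifact_onsets <- vector("list", length(channels))
    for (ch in seq_along(channels)) {
      x <- background_channel(n, fs, background)
      artifact_onsets[[ch]] <- attr(x, "artifact_onsets_s") %||% numeric(0)
      data[, ch] <- x
    }
  })

  if (evoked$amplitude_uv > 0) {
    m <- round(evoked$response_s * fs)
    rel_t <- evoked$onset_latency_s + (seq_len(m) - 1) / fs
    # trial x time matrix of the evoked sinusoid, phase jittered per trial
    ev <- evoked$amplitude_uv *
      cos(outer(phases, 2 * pi * evoked$carrier_freq * rel_t, `+`))
    starts <- round((onsets + evoked$onset_latency_s) * fs)
    evoked_sig <- numeric(n)
    for (j in seq_along(starts)) {
      idx <- (starts[j] + 1):(starts[j] + m)
      evoked_sig[idx] <- evoked_sig[idx] + ev[j, ]
    }
    data <- data + evoked_sig
  }

  rec <- eeg_recording(data, fs, channels)
  attr(rec, "trial_phases") <- phases
  attr(rec, "artifact_onsets_s") <- setNames(artifact_onsets, channels)
  attr(rec, "seed") <- seed
  list(recording = rec, events = event_series(onsets))
}

#' Simulate a stimulus-free (spontaneous) recording
#'
#' Same background composition as [simulate_assr_session()] but without any
#' stimulation: used for quantitative EEG band-power analysis. Doubling
#' `background$gamma_scale` multiplies the expected 32-80 Hz band power by
#' four (power scales with amplitude squared).
#'
#' @inheritParams simulate_assr_session
#' @param duration_s Recording duration, seconds (> 0).
#' @return An [eeg_recording()].
#' @export
simulate_spontaneous <- function(background, duration_s = 3600, fs = 1000,
                                 channels = c("global_cortex", "auditory_cortex"),
                                 seed = 1L) {
  stopifnot(inherits(background, "background_model"))
  check_number(duration_s, "duration_s", min = 0, strict_min = TRUE)
  if (fs < 2 * background$gamma_band[2]) {
    stop_config("fs below Nyquist rate for the gamma band")
  }
  n <- round(duration_s * fs)
  withr::with_seed(seed, {
    data <- matrix(0, n, length(channels))
    artifact_onsets <- vector("list", length(channels))
    for (ch in seq_along(channels)) {
      x <- background_channel(n, fs, background)
      artifact_onsets[[ch]] <- attr(x, "artifact_onsets_s") %||% numeric(0)
      data[, ch] <- x
    }
  })
  rec <- eeg_recording(data, fs, channels)
  attr(rec, "artifact_onsets_s") <- setNames(artifact_onsets, channels)
  attr(rec, "seed") <- seed
  rec
}

# Normal truncated to [lo, hi] by inverse-CDF; sd = 0 degenerates to the
# (clamped) mean.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) {
    return(pmin(pmax(rep(mean, n), lo), hi))
  }
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

#' Simulate behavioral tables for a study design
#'
#' Per-subject activity counts per time bin (negative-binomial around the
#' arm's mean profile) and per-pair social-interaction times (normal
#' truncated to `[0, test_duration]`). One pair per design subject.
#'
#' @param design A [study_design()].
#' @return A list of tibbles `activity` (subject, arm, bin, t0_min, t1_min,
#'   counts) and `social` (pair, arm, social_s, test_duration_s).
#' @export
simulate_behavior <- function(design) {
  stopifnot(inherits(design, "study_design"))
  withr::with_seed(design$seed + 1L, {
    act <- list()
    soc <- list()
    for (a in design$arms) {
      bm <- a$behavior
      mu <- bm$activity_mean_profile
      nb <- length(mu)
      for (s in seq_len(a$n_subjects)) {
        counts <- if (bm$activity_dispersion == 0) {
          rpois(nb, mu)
        } else {
          rnbinom(nb, size = 1 / bm$activity_dispersion, mu = mu)
        }
        act[[length(act) + 1L]] <- tibble(
          subject = sprintf("%s_%02d", a$label, s), arm = a$label,
          bin = seq_len(nb),
          t0_min = (seq_len(nb) - 1) * bm$activity_bin_min,
          t1_min = seq_len(nb) * bm$activity_bin_min,
          counts = as.integer(counts)
        )
      }
      soc[[length(soc) + 1L]] <- tibble(
        pair = sprintf("%s_pair%02d", a$label, seq_len(a$n_subjects)),
        arm = a$label,
        social_s = rtruncnorm(a$n_subjects, bm$social_mean_s, bm$social_sd_s,
                              0, bm$test_duration_s),
        test_duration_s = bm$test_duration_s
      )
    }
    list(activity = dplyr::bind_rows(act), social = dplyr::bind_rows(soc))
  })
}

#' Draw per-subject EEG generator parameters for a study design
#'
#' Realizes the between-subject heterogeneity of a design: each subject's
#' population PLF is drawn truncated-normal around the arm mean (when
#' `plf_mean` is set) and inverted to a von Mises concentration; the
#' background gamma amplitude gets a mean-preserving log-normal jitter with
#' coefficient of variation `gamma_cv`. Per-subject simulation seeds are
#' derived deterministically from the design seed.
#'
#' @param design A [study_design()].
#' @return Tibble (subject, arm, kappa, plf_pop, gamma_scale, seed).
#' @export
draw_subject_params <- function(design) {
  stopifnot(inherits(design, "study_design"))
  withr::with_seed(design$seed, {
    rows <- list()
    counter <- 0L
    for (a in design$arms) {
      nsub <- a$n_subjects
      if (is.null(a$plf_mean)) {
        plf_i <- rep(plf_population(a$evoked$kappa), nsub)
      } else {
        plf_i <- rtruncnorm(nsub, a$plf_mean, a$plf_sd, 0.01, 0.99)
      }
      g <- a$background$gamma_scale
      if (a$gamma_cv > 0 && g > 0) {
        sdlog <- sqrt(log(1 + a$gamma_cv^2))
        g_i <- g * exp(rnorm(nsub, -sdlog^2 / 2, sdlog))
      } else {
        g_i <- rep(g, nsub)
      }
      rows[[length(rows) + 1L]] <- tibble(
        subject = sprintf("%s_%02d", a$label, seq_len(nsub)),
        arm = a$label,
        plf_pop = plf_i,
        kappa = kappa_from_plf(plf_i),
        gamma_scale = g_i,
        seed = design$seed + 7919L * (counter + seq_len(nsub))
      )
      counter <- counter + nsub
    }
    dplyr::bind_rows(rows)
  })
}
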