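#' Auditory stimulation protocol
#'
#' Describes the periodic click-train stimulation used to evoke the auditory
#' steady-state response (ASSR): each stimulus is a click train of
#' `train_s` seconds at `click_rate` Hz followed by `silence_s` seconds of
#' silence. The defaults describe a 30-min session of 1500 stimuli
#' (0.5 s train + 0.7 s silence, 50-Hz click rate).
#'
#' @param n_stimuli Number of stimuli in the session.
#' @param train_s Click-train duration in seconds.
#' @param silence_s Silence duration after each train, seconds.
#' @param click_rate Click repetition rate within the train, Hz. This is the
#'   steady-state frequency the cortex entrains to.
#' @param start_offset_s Seconds of recording before the first stimulus onset
#'   (the same margin is appended after the last cycle).
#' @return An object of class `stim_protocol`.
#' @examples
#' p <- stim_protocol()
#' p$n_stimuli * (p$train_s + p$silence_s) / 60 # session core length, minutes
#' @export
stim_protocol <- function(n_stimuli = 1500, train_s = 0.5, silence_s = 0.7,
                          click_rate = 50, start_offset_s = 1) {
  check_number(n_stimuli, "n_stimuli", min = 1)
  check_number(train_s, "train_s", min = 0, strict_min = TRUE)
  check_number(silence_s, "silence_s", min = 0)
  check_number(click_rate, "click_rate", min = 0, strict_min = TRUE)
  check_number(start_offset_s, "start_offset_s", min = 0)
  structure(
    list(
      n_stimuli = as.integer(n_stimuli), train_s = train_s,
      silence_s = silence_s, click_rate = click_rate,
      start_offset_s = start_offset_s
    ),
    class = "stim_protocol"
  )
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf(
    "<stim_protocol> %d stimuli: %.3g-s train @ %g Hz + %.3g-s silence (cycle %.3g s)\n",
    x$n_stimuli, x$train_s, x$click_rate, x$train_s + x$silence_s
  ))
  invisible(x)
}

protocol_cycle_s <- function(p) p$train_s + p$silence_s

#' Evoked steady-state response model
#'
#' Generative model of the stimulus-locked component: a sinusoid at
#' `carrier_freq` whose phase is redrawn on every trial from a von Mises
#' distribution with concentration `kappa`. The population phase-locking
#' factor of this component is the mean resultant length
#' `I1(kappa)/I0(kappa)` (see [plf_population()]), which makes `kappa` the
#' single phase-synchrony knob with an analytic target for validation:
#' `kappa = 0` gives uniform phases (no locking), large `kappa` approaches
#' perfect locking.
#'
#' @param carrier_freq Response frequency, Hz (defaults to the 50-Hz train rate).
#' @param amplitude_uv Sinusoid amplitude, microvolts.
#' @param kappa Von Mises concentration of the trial-wise phase, >= 0.
#' @param onset_latency_s Response start relative to stimulus onset, seconds.
#' @param response_s Response duration, seconds.
#' @return An object of class `evoked_model`.
#' @export
evoked_model <- function(carrier_freq = 50, amplitude_uv = 30, kappa = 4,
                         onset_latency_s = 0, response_s = 0.5) {
  check_number(carrier_freq, "carrier_freq", min = 0, strict_min = TRUE)
  check_number(amplitude_uv, "amplitude_uv", min = 0)
  check_number(kappa, "kappa", min = 0)
  check_number(onset_latency_s, "onset_latency_s", min = 0)
  check_number(response_s, "response_s", min = 0, strict_min = TRUE)
  structure(
    list(
      carrier_freq = carrier_freq, amplitude_uv = amplitude_uv, kappa = kappa,
      onset_latency_s = onset_latency_s, response_s = response_s
    ),
    class = "evoked_model"
  )
}

#' Background EEG model
#'
#' Stationary background activity added to every simulated recording:
#' `1/f^alpha` ("pink") noise of RMS amplitude `pink_scale_uv`, a band-limited
#' 32-80 Hz noise component whose RMS amplitude is `gamma_scale` microvolts
#' (doubling `gamma_scale` multiplies the expected gamma band power by four),
#' and occasional large biphasic artifacts (200-ms, peak `artifact_amplitude_uv`,
#' peak-to-peak twice that) with Poisson timing at `artifact_rate_per_min`
#' events per minute.
#'
#' @param pink_exponent Spectral slope alpha of the 1/f^alpha component.
#' @param pink_scale_uv RMS amplitude of the pink component, microvolts.
#' @param gamma_scale RMS amplitude multiplier of the unit-RMS 32-80 Hz
#'   band-limited component (effectively microvolts RMS).
#' @param artifact_rate_per_min Expected artifact count per minute.
#' @param artifact_amplitude_uv Artifact peak amplitude, microvolts.
#' @param gamma_band Passband of the band-limited component, Hz.
#' @return An object of class `background_model`.
#' @export
background_model <- function(pink_exponent = 1, pink_scale_uv = 8,
                             gamma_scale = 15, artifact_rate_per_min = 0.5,
                             artifact_amplitude_uv = 600,
                             gamma_band = c(32, 80)) {
  check_number(pink_exponent, "pink_exponent", min = 0)
  check_number(pink_scale_uv, "pink_scale_uv", min = 0)
  check_number(gamma_scale, "gamma_scale", min = 0)
  check_number(artifact_rate_per_min, "artifact_rate_per_min", min = 0)
  check_number(artifact_amplitude_uv, "artifact_amplitude_uv", min = 0)
  if (length(gamma_band) != 2L || gamma_band[1] >= gamma_band[2]) {
    stop_config("`gamma_band` must be (f_lo, f_hi) with f_lo < f_hi")
  }
  structure(
    list(
      pink_exponent = pink_exponent, pink_scale_uv = pink_scale_uv,
      gamma_scale = gamma_scale, artifact_rate_per_min = artifact_rate_per_min,
      artifact_amplitude_uv = artifact_amplitude_uv, gamma_band = gamma_band
    ),
    class = "background_model"
  )
}

#' Behavioral endpoint model
#'
#' Generative model for the two behavioral endpoints: horizontal activity
#' counts per time bin (negative-binomial around a per-bin mean profile, with
#' overdispersion `activity_dispersion`; 0 recovers Poisson) and
#' social-interaction time per pair of animals (normal truncated to
#' `[0, test_duration_s]`).
#'
#' @param activity_bin_min Activity bin width, minutes.
#' @param activity_mean_profile Mean counts per bin (recycled or one value per
#'   bin), ordered from dosing time.
#' @param activity_dispersion Negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2).
#' @param social_mean_s Mean social-interaction time per pair, seconds.
#' @param social_sd_s Between-pair SD of social time, seconds.
#' @param test_duration_s Social test duration, seconds.
#' @return An object of class `behavior_model`.
#' @export
behavior_model <- function(activity_bin_min = 10,
                           activity_mean_profile = rep(31.9, 9),
                           activity_dispersion = 0.4,
                           social_mean_s = 57, social_sd_s = 11,
                           test_duration_s = 600) {
  check_number(activity_bin_min, "activity_bin_min", min = 0, strict_min = TRUE)
  if (any(activity_mean_profile < 0)) stop_config("activity means must be >= 0")
  check_number(activity_dispersion, "activity_dispersion", min = 0)
  check_number(social_mean_s, "social_mean_s", min = 0)
  check_number(social_sd_s, "social_sd_s", min = 0)
  check_number(test_duration_s, "test_duration_s", min = 0, strict_min = TRUE)
  structure(
    list(
      activity_bin_min = activity_bin_min,
      activity_mean_profile = as.numeric(activity_mean_profile),
      activity_dispersion = activity_dispersion,
      social_mean_s = social_mean_s, social_sd_s = social_sd_s,
      test_duration_s = test_duration_s
    ),
    class = "behavior_model"
  )
}

#' Treatment arm of a simulated study
#'
#' Bundles per-arm models and sample size. Phase synchrony can be specified
#' either through `evoked$kappa` (identical for all subjects) or, for
#' realistic between-subject spread, through `plf_mean`/`plf_sd`: each
#' subject's population phase-locking factor is then drawn from a normal
#' distribution truncated to (0.01, 0.99) and inverted to a von Mises
#' concentration.
#'
#' @param label Arm label (e.g. "vehicle", "MK-801").
#' @param n_subjects Subjects (EEG) and pairs (social test) in the arm.
#' @param evoked An [evoked_model()].
#' @param background A [background_model()].
#' @param behavior A [behavior_model()].
#' @param plf_mean Optional arm-mean population PLF in (0, 1); overrides
#'   `evoked$kappa` subject-wise when given.
#' @param plf_sd Between-subject SD of the population PLF (used with `plf_mean`).
#' @param gamma_cv Between-subject coefficient of variation of the background
#'   gamma amplitude (log-normal, mean-preserving).
#' @return An object of class `study_arm`.
#' @export
study_arm <- function(label, n_subjects = 8, evoked = evoked_model(),
                      background = background_model(),
                      behavior = behavior_model(),
                      plf_mean = NULL, plf_sd = 0.07, gamma_cv = 0.25) {
  stopifnot(is.character(label), length(label) == 1L)
  check_number(n_subjects, "n_subjects", min = 2)
  if (!is.null(plf_mean)) {
    check_number(plf_mean, "plf_mean", min = 0, max = 1, strict_min = TRUE)
    check_number(plf_sd, "plf_sd", min = 0)
  }
  check_number(gamma_cv, "gamma_cv", min = 0)
  structure(
    list(
      label = label, n_subjects = as.integer(n_subjects), evoked = evoked,
      background = background, behavior = behavior,
      plf_mean = plf_mean, plf_sd = plf_sd, gamma_cv = gamma_cv
    ),
    class = "study_arm"
  )
}

#' Study design: arms, reference arm, master seed
#'
#' @param arms List of [study_arm()] objects with unique labels.
#' @param reference_arm Label of the reference (control) arm; exactly one arm
#'   must carry it. Group statistics compare every other arm against it.
#' @param seed Integer master seed; all per-subject seeds derive from it.
#' @return An object of class `study_design`.
#' @export
study_design <- function(arms, reference_arm, seed = 1L) {
  labels <- vapply(arms, function(a) a$label, character(1))
  if (anyDuplicated(labels)) stop_config("arm labels must be unique")
  if (sum(labels == reference_arm) != 1L) {
    stop_config(sprintf("exactly one arm must be labelled '%s'", reference_arm))
  }
  check_number(seed, "seed")
  structure(
    list(arms = arms, reference_arm = reference_arm, seed = as.integer(seed)),
    class = "study_design"
  )
}

#' Canonical two-arm NMDA-antagonist study design
#'
#' Vehicle vs. drug design with effect sizes on the scale reported for acute
#' MK-801-type NMDA-receptor antagonism in rats: the drug arm's population
#' phase-locking factor is `plf_ratio` times the vehicle arm's (default 0.4,
#' i.e. ~40% of vehicle), its spontaneous background gamma amplitude is
#' `gamma_amp_ratio` times vehicle (default `sqrt(4.06)`, i.e. ~406% of
#' vehicle in band power), horizontal activity is strongly elevated
#' (arm means ~3334 vs ~287 counts per 90 min) and social interaction
#' reduced (~13.9 vs ~57 s per 600-s test).
#'
#' @param seed Master seed.
#' @param n_per_arm Subjects per arm.
#' @param plf_ratio Drug/vehicle population PLF ratio.
#' @param gamma_amp_ratio Drug/vehicle background gamma amplitude ratio.
#' @param vehicle_plf Vehicle-arm mean population PLF.
#' @param drug_label Label of the treated arm.
#' @return A [study_design()].
#' @export
default_assr_study <- function(seed = 1L, n_per_arm = 8, plf_ratio = 0.4,
                               gamma_amp_ratio = sqrt(4.06),
                               vehicle_plf = 0.85, drug_label = "MK-801") {
  bg <- background_model()
  veh <- study_arm(
    "vehicle", n_per_arm,
    background = bg, plf_mean = vehicle_plf,
    behavior = behavior_model(
      activity_mean_profile = rep(286.8 / 9, 9),
      social_mean_s = 57, social_sd_s = 11
    )
  )
  drg <- study_arm(
    drug_label, n_per_arm,
    background = background_model(gamma_scale = bg$gamma_scale * gamma_amp_ratio),
    plf_mean = vehicle_plf * plf_ratio, plf_sd = 0.05,
    behavior = behavior_model(
      activity_mean_profile = rep(3334 / 9, 9),
      social_mean_s = 13.9, social_sd_s = 5
    )
  )
  study_design(list(veh, drg), reference_arm = "vehicle", seed = seed)
}

#' Population phase-locking factor of a von Mises phase distribution
#'
#' Mean resultant length `I1(kappa)/I0(kappa)` of trial phases drawn from a
#' von Mises distribution with concentration `kappa`: the asymptotic PLF the
#' estimation pipeline must recover from a noise-free evoked component.
#'
#' @param kappa Concentration parameter(s), >= 0.
#' @return Numeric vector of resultant lengths in `[0, 1)`.
#' @examples
#' plf_population(c(0, 2, 4)) # 0, ~0.698, ~0.863
#' @export
plf_population <- function(kappa) {
  stopifnot(all(kappa >= 0))
  out <- numeric(length(kappa))
  big <- kappa > 50 # asymptotic form avoids besselI overflow
  out[big] <- 1 - 1 / (2 * kappa[big]) - 1 / (8 * kappa[big]^2)
  out[!big] <- ifelse(kappa[!big] == 0, 0,
    besselI(kappa[!big], 1) / besselI(kappa[!big], 0)
  )
  out
}

#' Von Mises concentration from a target population PLF
#'
#' Inverse of [plf_population()], solved numerically.
#'
#' @param plf Target mean resultant length in `[0, 1)`.
#' @return Concentration `kappa >= 0`.
#' @export
kappa_from_plf <- function(plf) {
  vapply(plf, function(r) {
    check_number(r, "plf", min = 0, max = 1 - 1e-9)
    if (r == 0) return(0)
    stats::uniroot(
      function(k) plf_population(k) - r,
      lower = 1e-9, upper = 2000, tol = 1e-10
    )$root
  }, numeric(1))
}

#' Expected resultant length of N uniform phases
#'
#' The small-sample positive bias of the phase-locking factor: with N
#' uniformly distributed phases the expected magnitude of the mean unit
#' phasor is `sqrt(pi) / (2 * sqrt(N))` (Rayleigh resultant expectation).
#'
#' @param n Number of epochs.
#' @return Expected PLF under no phase locking.
#' @examples
#' rayleigh_plf_expectation(1500) # ~0.0229
#' @export
rayleigh_plf_expectation <- function(n) sqrt(pi) / (2 * sqrt(n))
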