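# Orchestration: a single structured config holding every stage default
# (all anchored to the published analysis constants), YAML round-trip, and
# run_study() tying simulate -> ASSR -> qEEG -> behavior -> stats together
# with a provenance record.

#' Pipeline configuration
#'
#' Stage parameters with defaults equal to the published analysis constants:
#' 1500 stimuli of 0.5-s train + 0.7-s silence at 50 Hz; 1.5-s epochs
#' `[-0.5, +1.0]` s around the trigger; +/-300 uV sample rejection; 9-cycle
#' Morlet wavelets on `[48, 52]` Hz; 100-ms window trim; 4-s qEEG epochs
#' with 400-uV peak-to-peak rejection and the 32-80 Hz band over a 1-h
#' spontaneous recording; 90-min activity window; 2-SD outlier removal.
#' Every value is overridable.
#'
#' @param fs Sampling rate, Hz.
#' @param channels Simulated channel labels.
#' @param protocol Stimulation parameters (see [stim_protocol()]).
#' @param assr ASSR-stage parameters: `window`, `reject_uv`, `freqs`,
#'   `n_cycles`, `bl_window`, `roi_window`, `trim_s`.
#' @param qeeg qEEG-stage parameters: `duration_s`, `epoch_s`, `p2p_uv`,
#'   `band`.
#' @param behavior Behavior-stage parameters: `activity_window` (minutes).
#' @param stats Statistics parameters: `outlier_sd`.
#' @return A validated list of class `pipeline_config` (schema version 1).
#' @export
pipeline_config <- function(fs = 1000,
                            channels = c("global_cortex", "auditory_cortex"),
                            protocol = list(),
                            assr = list(), qeeg = list(),
                            behavior = list(), stats = list()) {
  merge_defaults <- function(user, defaults) {
    utils::modifyList(defaults, user[intersect(names(user), names(defaults))])
  }
  cfg <- list(
    schema_version = 1L,
    fs = fs,
    channels = channels,
    protocol = merge_defaults(protocol, list(
      n_stimuli = 1500L, train_s = 0.5, silence_s = 0.7, click_rate = 50,
      start_offset_s = 1
    )),
    assr = merge_defaults(assr, list(
      window = c(-0.5, 1), reject_uv = 300, freqs = seq(48, 52, by = 0.5),
      n_cycles = 9, bl_window = c(-0.5, 0), roi_window = c(0, 0.5),
      trim_s = 0.1
    )),
    qeeg = merge_defaults(qeeg, list(
      duration_s = 3600, epoch_s = 4, p2p_uv = 400, band = c(32, 80)
    )),
    behavior = merge_defaults(behavior, list(activity_window = c(0, 90))),
    stats = merge_defaults(stats, list(outlier_sd = 2))
  )
  check_number(cfg$fs, "fs", min = 0, strict_min = TRUE)
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration (YAML)
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (!identical(as.integer(raw$schema_version %||% 1L), 1L)) {
    stop_config(sprintf("unsupported config schema version: %s", raw$schema_version))
  }
  pipeline_config(
    fs = raw$fs %||% 1000,
    channels = unlist(raw$channels %||% c("global_cortex", "auditory_cortex")),
    protocol = lapply(raw$protocol %||% list(), unlist),
    assr = lapply(raw$assr %||% list(), unlist),
    qeeg = lapply(raw$qeeg %||% list(), unlist),
    behavior = lapply(raw$behavior %||% list(), unlist),
    stats = lapply(raw$stats %||% list(), unlist)
  )
}

config_protocol <- function(cfg) {
  stim_protocol(
    n_stimuli = cfg$protocol$n_stimuli, train_s = cfg$protocol$train_s,
    silence_s = cfg$protocol$silence_s, click_rate = cfg$protocol$click_rate,
    start_offset_s = cfg$protocol$start_offset_s
  )
}

#' ASSR endpoint for a single session
#'
#' The single-session analysis chain: epoch extraction around the triggers,
#' offset correction, +/- threshold rejection, Morlet PLF, ROI-minus-baseline
#' contrast.
#'
#' @param rec An [eeg_recording()].
#' @param events An [event_series()].
#' @param config A [pipeline_config()].
#' @return The [plf_contrast()] tibble with per-stage counts as attribute
#'   `"counts"`.
#' @export
assr_endpoint <- function(rec, events, config = pipeline_config()) {
  a <- config$assr
  es <- extract_epochs(rec, events, window = a$window)
  es <- offset_correct(es)
  es <- reject_epochs_amplitude(es, threshold_uv = a$reject_uv)
  map <- plf(es, freqs = a$freqs, n_cycles = a$n_cycles)
  ct <- plf_contrast(map, bl_window = a$bl_window, roi_window = a$roi_window,
                     trim_s = a$trim_s)
  attr(ct, "counts") <- c(
    events = nrow(events), extracted = n_epochs(es),
    dropped = es$n_dropped_events, rejected = sum(es$rejected),
    used = n_retained(es)
  )
  ct
}

#' Gamma band-power endpoint for a spontaneous recording
#'
#' Fixed 4-s segmentation, peak-to-peak rejection, Hanning periodogram,
#' summed 32-80 Hz power averaged over retained epochs.
#'
#' @param rec An [eeg_recording()] (no stimulation).
#' @param config A [pipeline_config()].
#' @return The session tibble of [band_power()] with per-stage counts as
#'   attribute `"counts"`.
#' @export
qeeg_endpoint <- function(rec, config = pipeline_config()) {
  q <- config$qeeg
  es <- segment_epochs(rec, epoch_s = q$epoch_s)
  es <- reject_epochs_p2p(es, threshold_uv = q$p2p_uv)
  bp <- band_power(power_spectrum(es), band = q$band)
  out <- bp$session
  attr(out, "counts") <- c(
    segmented = n_epochs(es), rejected = sum(es$rejected),
    used = n_retained(es)
  )
  out
}

#' Run a complete synthetic study through the pipeline
#'
#' For every subject of every arm: simulates an ASSR session and a
#' spontaneous recording with that subject's drawn parameters, computes the
#' PLF contrast and gamma band power per channel, simulates the behavioral
#' tables, aggregates the activity and social endpoints, and feeds all
#' endpoints through outlier removal, percent-of-reference normalization
#' and the ANOVA/Dunnett layer. Fully deterministic given the design seed.
#'
#' @param design A [study_design()].
#' @param config A [pipeline_config()].
#' @param stages Which endpoint families to compute (any of `"assr"`,
#'   `"qeeg"`, `"behavior"`); restricting them shortens simulation studies
#'   that target a single endpoint.
#' @return An object of class `assr_study`: `report` (the [build_report()]
#'   table), `endpoints` (raw per-subject endpoint tibbles), `subjects`
#'   (drawn parameters), and `provenance` (config hash, seed, version,
#'   per-stage counts).
#' @export
run_study <- function(design, config = pipeline_config(),
                      stages = c("assr", "qeeg", "behavior")) {
  stopifnot(inherits(design, "study_design"))
  stages <- match.arg(stages, several.ok = TRUE)
  protocol <- config_protocol(config)
  subjects <- draw_subject_params(design)
  arm_lookup <- setNames(design$arms, vapply(design$arms, `[[`, "", "label"))

  plf_rows <- list()
  gamma_rows <- list()
  counts <- list()
  for (i in seq_len(nrow(subjects))) {
    s <- subjects[i, ]
    arm <- arm_lookup[[s$arm]]
    evoked <- arm$evoked
    evoked$kappa <- s$kappa
    bg <- arm$background
    bg$gamma_scale <- s$gamma_scale

    subj_counts <- list()
    if ("assr" %in% stages) {
      sess <- simulate_assr_session(protocol, evoked, bg, fs = config$fs,
                                    channels = config$channels, seed = s$seed)
      ct <- assr_endpoint(sess$recording, sess$events, config)
      plf_rows[[i]] <- dplyr::mutate(
        dplyr::select(ct, "channel", value = "contrast"),
        subject = s$subject, arm = s$arm, .before = 1
      )
      subj_counts$assr <- attr(ct, "counts")
    }
    if ("qeeg" %in% stages) {
      spont <- simulate_spontaneous(bg, duration_s = config$qeeg$duration_s,
                                    fs = config$fs, channels = config$channels,
                                    seed = s$seed + 1L)
      gp <- qeeg_endpoint(spont, config)
      gamma_rows[[i]] <- tibble(
        subject = s$subject, arm = s$arm,
        channel = gp$channel, value = gp$band_power
      )
      subj_counts$qeeg <- attr(gp, "counts")
    }
    counts[[s$subject]] <- subj_counts
  }

  endpoints <- list()
  if ("assr" %in% stages) endpoints$assr_plf <- dplyr::bind_rows(plf_rows)
  if ("qeeg" %in% stages) endpoints$gamma_power <- dplyr::bind_rows(gamma_rows)
  if ("behavior" %in% stages) {
    beh <- simulate_behavior(design)
    endpoints$activity <- activity_sum(beh$activity,
                                       window = config$behavior$activity_window)
    social <- social_endpoint(beh$social)
    endpoints$social <- dplyr::select(social, subject = "pair", "arm", "value")
  }
  report <- build_report(endpoints, reference = design$reference_arm,
                         outlier_sd = config$stats$outlier_sd)
  structure(
    list(
      report = report, endpoints = endpoints, subjects = subjects,
      provenance = list(
        config_hash = rlang::hash(unclass(config)),
        seed = design$seed,
        package_version = as.character(utils::packageVersion("gammassr")),
        reference_arm = design$reference_arm,
        stage_counts = counts
      )
    ),
    class = "assr_study"
  )
}

#' @export
print.assr_study <- function(x, ...) {
  cat(sprintf("<assr_study> %d subjects, %d endpoint rows (seed %d)\n",
              nrow(x$subjects), nrow(x$report), x$provenance$seed))
  print(as.data.frame(dplyr::select(
    x$report, "endpoint", "channel", "arm", "n", "pct_mean", "pct_sem",
    "dunnett_p", "stars"
  )), digits = 4)
  invisible(x)
}
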