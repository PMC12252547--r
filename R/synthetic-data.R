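#' Deterministic child seed from a master seed
#'
#' All generator randomness flows from one master seed; sub-generators
#' (days, units, resampling repeats) draw from child streams derived by a
#' fixed integer recurrence, so any component is reproducible in
#' isolation.
#'
#' @param seed Master seed (integer).
#' @param index Child index (integer >= 0).
#' @return Integer seed below 2^31.
#' @export
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(index)) %% 2147483647)
}

#' Behavior generator configuration
#'
#' Defines the task conditions the generator emulates: daily sessions of
#' the two-alternative auditory discrimination task with trials every 20 s,
#' cue then lever insertion 3 s later, a press within the response window,
#' reward sound after a 0.5 +/- 0.2 s delay on correct trials, and a ~7-Hz
#' lick burst. The probability of following the stimulus rule grows across
#' days along the four-parameter logistic curve; errors can instead be
#' produced by a lose-shift habit (pressing the lever opposite the previous
#' press after an error).
#'
#' @param n_days Number of daily sessions (default 14).
#' @param trials_per_day Trials per session (default 180: a 60-min session
#'   at one trial per 20 s).
#' @param alpha,beta,gamma,lambda Logistic parameters of the
#'   stimulus-following probability by day (defaults 7, 0.8, 0.5, 0.95:
#'   chance-level start, near-perfect asymptote, inflection in week two).
#' @param omission_prob Per-trial omission probability (default 0.05).
#' @param lose_shift_prob After an error, probability of pressing the
#'   opposite lever regardless of the cue (default 0.2).
#' @param seed Master seed.
#' @return A `behavior_config` list.
#' @export
behavior_config <- function(n_days = 14, trials_per_day = 180, alpha = 7,
                            beta = 0.8, gamma = 0.5, lambda = 0.95,
                            omission_prob = 0.05, lose_shift_prob = 0.2,
                            seed = 1L) {
  if (omission_prob < 0 || omission_prob >= 1)
    abort("config error: omission_prob must lie in [0, 1)")
  if (lose_shift_prob < 0 || lose_shift_prob > 1)
    abort("config error: lose_shift_prob must lie in [0, 1]")
  if (!(gamma >= 0 && gamma <= lambda && lambda <= 1))
    abort("config error: need 0 <= gamma <= lambda <= 1")
  if (beta <= 0) abort("config error: beta must be positive")
  structure(as.list(environment()), class = "behavior_config")
}

.round_t <- function(x) round(x, .time_digits)

.trial_period_s <- 20
.lever_delay_s <- 3
.lick_rate_hz <- 7
.lick_burst_s <- 3

# one day's trials + licks; RNG state is the caller's responsibility
.generate_day <- function(cfg, day) {
  n <- cfg$trials_per_day
  n_blocks <- ceiling(n / 4)
  cue <- unlist(lapply(seq_len(n_blocks),
                       function(b) sample(c("high", "high", "low", "low"))))
  cue <- cue[seq_len(n)]
  f_day <- logistic4(day, cfg$alpha, cfg$beta, cfg$gamma, cfg$lambda)
  correct_lever <- ifelse(cue == "high", "right", "left")
  other_lever <- ifelse(cue == "high", "left", "right")
  response <- character(n)
  prev_outcome <- NA_character_
  prev_response <- NA_character_
  for (t in seq_len(n)) {
    if (runif(1) < cfg$omission_prob) {
      response[t] <- "none"
    } else if (!is.na(prev_outcome) && prev_outcome == "error" &&
               runif(1) < cfg$lose_shift_prob) {
      response[t] <- setdiff(c("right", "left"), prev_response)
    } else if (runif(1) < f_day) {
      response[t] <- correct_lever[t]
    } else {
      response[t] <- other_lever[t]
    }
    if (response[t] != "none") {
      prev_outcome <- if (response[t] == correct_lever[t]) "correct" else "error"
      prev_response <- response[t]
    } else {
      prev_outcome <- "omission"
    }
  }
  outcome <- dplyr::case_when(
    response == "none" ~ "omission",
    response == correct_lever ~ "correct",
    TRUE ~ "error"
  )
  cue_time <- (seq_len(n) - 1) * .trial_period_s
  lever_time <- cue_time + .lever_delay_s
  press_time <- ifelse(response == "none", NA_real_,
                       lever_time + runif(n, 0.3, 2.0))
  reward_time <- ifelse(outcome == "correct",
                        press_time + runif(n, 0.3, 0.7), NA_real_)
  licks <- list()
  first_lick <- rep(NA_real_, n)
  for (t in which(outcome == "correct")) {
    burst0 <- reward_time[t] + runif(1, 0.1, 0.3)
    lt <- burst0 + seq(0, .lick_burst_s, by = 1 / .lick_rate_hz) +
      stats::rnorm(ceiling(.lick_burst_s * .lick_rate_hz) + 1, 0, 0.005)
    lt <- sort(lt[lt >= burst0])
    first_lick[t] <- lt[1]
    licks[[length(licks) + 1]] <- lt
  }
  list(
    trials = tibble(
      session_day = as.integer(day), trial_index = seq_len(n), cue = cue,
      cue_time_s = .round_t(cue_time), lever_insert_time_s = .round_t(lever_time),
      response = response, press_time_s = .round_t(press_time),
      outcome = outcome, reward_sound_time_s = .round_t(reward_time),
      first_lick_time_s = .round_t(first_lick)
    ),
    licks = tibble(session_day = as.integer(day),
                   lick_time_s = .round_t(sort(unlist(licks) %||% double())))
  )
}

#' Generate task behavior
#'
#' Simulates every daily session of a discrimination-learning experiment
#' under a [behavior_config()]: pseudorandom cues with equal frequency per
#' 4-trial block, omissions, a lose-shift error habit, stimulus-following
#' with probability given by the logistic curve, reward-sound delay on
#' correct trials, and lick bursts. Deterministic given the config seed.
#'
#' @param cfg A `behavior_config`.
#' @return List with tibbles `trials` and `licks` covering all days.
#' @export
generate_behavior <- function(cfg) {
  stopifnot(inherits(cfg, "behavior_config"))
  days <- purrr::map(seq_len(cfg$n_days), function(day) {
    set.seed(child_seed(cfg$seed, day))
    .generate_day(cfg, day)
  })
  list(
    trials = purrr::list_rbind(purrr::map(days, "trials")),
    licks = purrr::list_rbind(purrr::map(days, "licks"))
  )
}

#' Event-locked rate kernel specification
#'
#' @param event Anchoring event (`"cue_onset"`, `"choice_response"`,
#'   `"reward_sound"`, `"first_licking"`).
#' @param gain_hz Added rate at the kernel peak (boxcar: throughout).
#' @param onset_ms,duration_ms Kernel support relative to the event.
#' @param trial_types Trial types the kernel applies to (subset of
#'   HR/LL/HL/LR; default all).
#' @param shape `"boxcar"` (constant) or `"alpha"` (fast rise, slow
#'   decay, peak gain `gain_hz`).
#' @return One-row kernel tibble; rows can be stacked.
#' @export
rate_kernel <- function(event, gain_hz, onset_ms = 0, duration_ms = 1000,
                        trial_types = c("HR", "LL", "HL", "LR"),
                        shape = c("boxcar", "alpha")) {
  shape <- match.arg(shape)
  stopifnot(gain_hz >= 0, duration_ms > 0)
  tibble(event = event, gain_hz = gain_hz, onset_ms = onset_ms,
         duration_ms = duration_ms, trial_types = list(trial_types),
         shape = shape)
}

#' Unit generator configuration
#'
#' Spike trains are drawn from an inhomogeneous Poisson process (baseline
#' plus event-locked kernels) thinned by an absolute dead time, with
#' optional quiescent pauses (a two-state rate switch) that control the
#' long-ISI proportion. Per-class presets place every classification
#' metric at least twofold beyond its threshold: MSNs are wide-waveform
#' (1.2 ms), low-rate (3 Hz) with long post-spike suppression (80 ms);
#' TANs wide (1.3 ms), tonic (5 Hz), short suppression (12 ms); FSIs
#' narrow (0.25 ms), fast (15 Hz); UIs narrow (0.3 ms), sparse (2 Hz)
#' with ~80% quiescence from 10-s pauses.
#'
#' @param cell_class Target class preset (`"MSN"`, `"FSI"`, `"TAN"`,
#'   `"UI"`).
#' @param baseline_rate_hz Baseline rate (Hz); `NULL` uses the preset.
#' @param kernels Kernel tibble from stacked [rate_kernel()] rows (default
#'   none).
#' @param dead_time_ms Absolute post-spike dead time; `NULL` uses preset.
#' @param pause_rate_hz Rate of quiescent-pause onsets (Hz).
#' @param pause_duration_s Duration of each pause (s).
#' @param trough_to_peak_ms Waveform width; `NULL` uses preset.
#' @param region Recording region label (default `"aDLS"`).
#' @param session_day Day whose behavior drives the kernels (default 1).
#' @param l_ratio,isolation_distance,isi_index Quality metrics written to
#'   the unit record (defaults pass the filter).
#' @param seed Seed for this unit's spike train.
#' @return A `unit_config` list.
#' @export
unit_config <- function(cell_class = c("MSN", "FSI", "TAN", "UI"),
                        baseline_rate_hz = NULL, kernels = NULL,
                        dead_time_ms = NULL, pause_rate_hz = NULL,
                        pause_duration_s = NULL, trough_to_peak_ms = NULL,
                        region = "aDLS", session_day = 1L, l_ratio = 0.01,
                        isolation_distance = 30, isi_index = 0.05,
                        seed = 1L) {
  cell_class <- match.arg(cell_class)
  preset <- switch(cell_class,
    MSN = list(rate = 3, dead = 80, pause_rate = 0, pause_dur = 0, ttp = 1.2),
    TAN = list(rate = 5, dead = 12, pause_rate = 0, pause_dur = 0, ttp = 1.3),
    FSI = list(rate = 15, dead = 2, pause_rate = 0, pause_dur = 0, ttp = 0.25),
    UI = list(rate = 2, dead = 2, pause_rate = 0.161, pause_dur = 10, ttp = 0.3)
  )
  cfg <- list(
    cell_class = cell_class,
    baseline_rate_hz = baseline_rate_hz %||% preset$rate,
    kernels = kernels %||% rate_kernel("cue_onset", 0)[0, ],
    dead_time_ms = dead_time_ms %||% preset$dead,
    pause_rate_hz = pause_rate_hz %||% preset$pause_rate,
    pause_duration_s = pause_duration_s %||% preset$pause_dur,
    trough_to_peak_ms = trough_to_peak_ms %||% preset$ttp,
    region = region, session_day = as.integer(session_day),
    l_ratio = l_ratio, isolation_distance = isolation_distance,
    isi_index = isi_index, seed = seed
  )
  if (cfg$baseline_rate_hz < 0 || any(cfg$kernels$gain_hz < 0))
    abort("config error: rates must be non-negative")
  if (cfg$dead_time_ms < 0) abort("config error: dead time must be >= 0")
  structure(cfg, class = "unit_config")
}

# piecewise rate above baseline from kernels at the matching trial events
.kernel_intervals <- function(kernels, trials) {
  typed <- classify_trials(trials)
  purrr::map(seq_len(nrow(kernels)), function(j) {
    k <- kernels[j, ]
    tt <- k$trial_types[[1]]
    col <- .event_time_col[[k$event]]
    ev <- typed |>
      filter(!is.na(.data$trial_type), .data$trial_type %in% tt,
             !is.na(.data[[col]]))
    if (nrow(ev) == 0) return(NULL)
    tibble(start = ev[[col]] + k$onset_ms / 1000,
           end = ev[[col]] + (k$onset_ms + k$duration_ms) / 1000,
           gain = k$gain_hz, shape = k$shape,
           duration_s = k$duration_ms / 1000)
  }) |> purrr::list_rbind()
}

.rate_at <- function(t, baseline, intervals) {
  rate <- rep(baseline, length(t))
  if (is.null(intervals) || nrow(intervals) == 0) return(rate)
  for (j in seq_len(nrow(intervals))) {
    iv <- intervals[j, ]
    inside <- t >= iv$start & t < iv$end
    if (!any(inside)) next
    if (iv$shape == "boxcar") {
      rate[inside] <- rate[inside] + iv$gain
    } else {
      tau <- iv$duration_s / 4
      u <- (t[inside] - iv$start) / tau
      rate[inside] <- rate[inside] + iv$gain * u * exp(1 - u)
    }
  }
  rate
}

.synth_waveform <- function(trough_to_peak_ms, sampling_rate_hz = 20000,
                            n_samples = 64) {
  trough_i <- 20
  peak_i <- trough_i + round(trough_to_peak_ms * sampling_rate_hz / 1000)
  stopifnot(peak_i < n_samples, peak_i > trough_i)
  i <- seq_len(n_samples)
  # narrow triangular trough and repolarization bump with sample-exact
  # extrema, so the configured width is recovered to within one sample
  tri <- function(center, half_width, height) {
    height * pmax(0, 1 - abs(i - center) / half_width)
  }
  amp <- -tri(trough_i, 2.5, 100) +
    tri(peak_i, max(2.5, (peak_i - trough_i) / 2), 35)
  tibble(sample_index = i, amplitude_uv = amp)
}

#' Generate one unit's spike train and template
#'
#' Draws an inhomogeneous Poisson spike train over the session span (rate
#' = baseline + active kernels) by thinning a homogeneous process at the
#' rate ceiling, silences quiescent pauses (Poisson pause onsets of fixed
#' duration), and enforces the absolute dead time sequentially.
#' Deterministic given the config seed.
#'
#' @param cfg A `unit_config`.
#' @param trials Trials tibble of the unit's session day.
#' @param unit_id Identifier to stamp on the outputs.
#' @return List with `unit` (one-row units tibble), `spikes`, `waveform`.
#' @export
generate_unit <- function(cfg, trials, unit_id = "u001") {
  stopifnot(inherits(cfg, "unit_config"))
  set.seed(cfg$seed)
  rec_start <- 0
  rec_end <- max(trials$cue_time_s) + .trial_period_s
  span <- rec_end - rec_start
  intervals <- .kernel_intervals(cfg$kernels, trials)
  rate_max <- cfg$baseline_rate_hz +
    sum(cfg$kernels$gain_hz[cfg$kernels$gain_hz > 0])
  spikes <- double(0)
  if (rate_max > 0) {
    n_cand <- rpois(1, rate_max * span)
    cand <- sort(runif(n_cand, rec_start, rec_end))
    keep <- runif(n_cand) < .rate_at(cand, cfg$baseline_rate_hz, intervals) / rate_max
    spikes <- cand[keep]
  }
  if (cfg$pause_rate_hz > 0 && cfg$pause_duration_s > 0 && length(spikes)) {
    n_pause <- rpois(1, cfg$pause_rate_hz * span)
    p0 <- runif(n_pause, rec_start, rec_end)
    in_pause <- rep(FALSE, length(spikes))
    for (p in p0) in_pause <- in_pause | (spikes >= p & spikes < p + cfg$pause_duration_s)
    spikes <- spikes[!in_pause]
  }
  if (cfg$dead_time_ms > 0 && length(spikes) > 1) {
    dead_s <- cfg$dead_time_ms / 1000
    keep <- logical(length(spikes))
    last <- -Inf
    for (i in seq_along(spikes)) {
      if (spikes[i] - last >= dead_s) { keep[i] <- TRUE; last <- spikes[i] }
    }
    spikes <- spikes[keep]
  }
  spikes <- .round_t(spikes)
  list(
    unit = tibble(
      unit_id = unit_id, region = cfg$region, session_day = cfg$session_day,
      recording_start_s = rec_start, recording_end_s = .round_t(rec_end),
      sampling_rate_hz = 20000, l_ratio = cfg$l_ratio,
      isolation_distance = cfg$isolation_distance, isi_index = cfg$isi_index
    ),
    spikes = tibble(unit_id = unit_id, spike_time_s = spikes),
    waveform = mutate(.synth_waveform(cfg$trough_to_peak_ms),
                      unit_id = unit_id, .before = 1)
  )
}

#' Generate a full synthetic cohort
#'
#' Composes [generate_behavior()] with one [generate_unit()] per config:
#' the behavior is generated from the master seed and each unit draws its
#' spike train from a derived child seed (overriding per-config seeds), so
#' the same master seed always yields an identical bundle.
#'
#' @param behavior_cfg A [behavior_config()].
#' @param unit_cfgs List of [unit_config()]s (may be empty).
#' @param seed Master seed (default: the behavior config's seed).
#' @return A validated `session_bundle`; the generator configuration is
#'   kept in `metadata`.
#' @export
generate_cohort <- function(behavior_cfg, unit_cfgs = list(), seed = NULL) {
  seed <- seed %||% behavior_cfg$seed
  behavior_cfg$seed <- seed
  beh <- generate_behavior(behavior_cfg)
  parts <- purrr::map(seq_along(unit_cfgs), function(i) {
    cfg <- unit_cfgs[[i]]
    cfg$seed <- child_seed(seed, 100000 + i)
    day_trials <- filter(beh$trials, .data$session_day == cfg$session_day)
    if (nrow(day_trials) == 0)
      abort(sprintf("unit config %d: session day %d has no behavior", i,
                    cfg$session_day))
    generate_unit(cfg, day_trials, unit_id = sprintf("u%04d", i))
  })
  bind_or_empty <- function(field, empty) {
    if (length(parts) == 0) empty
    else purrr::list_rbind(purrr::map(parts, field))
  }
  session_bundle(
    trials = beh$trials, licks = beh$licks,
    spikes = bind_or_empty("spikes", empty_spikes()),
    units = bind_or_empty("unit", empty_units()),
    waveforms = bind_or_empty("waveform", empty_waveforms()),
    metadata = list(seed = seed, n_units = length(unit_cfgs),
                    behavior_config = unclass(behavior_cfg))
  )
}
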