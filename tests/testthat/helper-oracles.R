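# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# literal per-trial predicate enumeration for WSW / LSL
oracle_strategies <- function(trials) {
  trials <- trials[order(trials$trial_index), ]
  n_wsw <- 0L
  n_lsl <- 0L
  for (t in seq_len(nrow(trials))) {
    if (t == 1) next
    prev <- trials[t - 1, ]
    cur <- trials[t, ]
    if (prev$outcome == "omission" || cur$outcome == "omission") next
    shift <- cur$cue != prev$cue && cur$response != prev$response
    if (shift && prev$outcome == "correct" && cur$outcome == "correct")
      n_wsw <- n_wsw + 1L
    if (shift && prev$outcome == "error" && cur$outcome == "error")
      n_lsl <- n_lsl + 1L
  }
  n_completed <- sum(trials$outcome != "omission")
  list(n_wsw = n_wsw, n_lsl = n_lsl,
       prop_wsw = n_wsw / n_completed, prop_lsl = n_lsl / n_completed)
}

# exhaustive pair counting with the tie rule
oracle_auroc <- function(a, b) {
  wins <- 0
  for (x in a) for (y in b) {
    if (x > y) wins <- wins + 1
    else if (x == y) wins <- wins + 0.5
  }
  wins / (length(a) * length(b))
}

# naive double-loop spike counter over [start, end)
oracle_count_spikes <- function(spike_times, event_times, start_s, end_s) {
  out <- integer(length(event_times))
  for (i in seq_along(event_times)) {
    k <- 0L
    for (s in spike_times) {
      if (s >= event_times[i] + start_s && s < event_times[i] + end_s)
        k <- k + 1L
    }
    out[i] <- k
  }
  out
}

# a random but internally consistent session (omissions included)
random_session <- function(n_trials, day = 1L, omission_prob = 0.15) {
  cue <- sample(c("high", "low"), n_trials, replace = TRUE)
  response <- ifelse(runif(n_trials) < omission_prob, "none",
                     sample(c("right", "left"), n_trials, replace = TRUE))
  outcome <- ifelse(
    response == "none", "omission",
    ifelse((cue == "high" & response == "right") |
             (cue == "low" & response == "left"), "correct", "error")
  )
  cue_time <- (seq_len(n_trials) - 1) * 20
  press <- ifelse(response == "none", NA_real_, cue_time + 3 + runif(n_trials, 0.3, 2))
  reward <- ifelse(outcome == "correct", press + runif(n_trials, 0.3, 0.7), NA_real_)
  tibble::tibble(
    session_day = day, trial_index = seq_len(n_trials), cue = cue,
    cue_time_s = cue_time, lever_insert_time_s = cue_time + 3,
    response = response, press_time_s = press, outcome = outcome,
    reward_sound_time_s = reward,
    first_lick_time_s = ifelse(is.na(reward), NA_real_, reward + 0.2)
  )
}

# fabricate a converged learning fit with chosen parameters
make_fit <- function(alpha, beta, gamma = 0.5, lambda = 0.95) {
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma, lambda = lambda,
         rss = 0, converged = TRUE, degenerate = FALSE,
         data = tibble::tibble(session_day = 1:14,
                               success_rate = rep(0.5, 14))),
    class = "learning_fit"
  )
}

# a fit whose t20/t90 crossing days equal the requested integers
make_fit_with_days <- function(t20, t90) {
  beta <- log(36) / (t90 - t20)
  alpha <- (t20 - 0.5) + log(4) / beta
  fit <- make_fit(alpha, beta)
  stopifnot(threshold_crossing_day(fit, 0.2) == t20,
            threshold_crossing_day(fit, 0.9) == t90)
  fit
}

# small cohort: one day of near-perfect task behavior plus n units,
# a fraction of them with a strong cue-onset response
planted_cohort <- function(n_units, frac_responsive, trials_per_day = 60,
                           gain_hz = 15, baseline_hz = 5, seed = 1L,
                           n_days = 1L) {
  bcfg <- behavior_config(
    n_days = n_days, trials_per_day = trials_per_day, gamma = 1, lambda = 1,
    omission_prob = 0, lose_shift_prob = 0, seed = seed
  )
  n_resp <- round(n_units * frac_responsive)
  ucfgs <- lapply(seq_len(n_units), function(i) {
    kern <- if (i <= n_resp) {
      rate_kernel("cue_onset", gain_hz, 0, 1000, trial_types = c("HR", "LL"))
    } else NULL
    unit_config("MSN", baseline_rate_hz = baseline_hz, kernels = kern,
                dead_time_ms = 0, session_day = 1L)
  })
  generate_cohort(bcfg, ucfgs, seed = seed)
}
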