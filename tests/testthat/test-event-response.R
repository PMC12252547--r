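test_that("trial typing crosses cue with press and skips omissions", {
  tr <- tibble::tibble(
    session_day = 1L, trial_index = 1:5,
    cue = c("high", "low", "high", "low", "high"),
    cue_time_s = 0:4 * 20, lever_insert_time_s = 0:4 * 20 + 3,
    response = c("right", "left", "left", "right", "none"),
    press_time_s = c(4, 24, 44, 64, NA),
    outcome = c("correct", "correct", "error", "error", "omission"),
    reward_sound_time_s = c(4.5, 24.5, NA, NA, NA),
    first_lick_time_s = c(4.8, 24.8, NA, NA, NA)
  )
  typed <- classify_trials(tr)
  expect_equal(typed$trial_type, c("HR", "LL", "HL", "LR", NA))
})

test_that("spike counting uses half-open windows and matches the naive loop", {
  expect_equal(count_spikes(c(1.0, 1.5), 1.0, 0, 1), 2L)
  expect_equal(count_spikes(c(1.0, 1.5), 1.0, 0, 0.5), 1L)  # end excluded
  expect_equal(count_spikes(numeric(0), c(1, 2, 3), 0, 1), c(0L, 0L, 0L))
  withr::local_seed(42)
  for (i in 1:25) {
    st <- sort(runif(200, 0, 100))
    ev <- runif(10, 5, 95)
    a <- runif(1, -2, 0); b <- a + runif(1, 0.1, 3)
    expect_equal(count_spikes(st, ev, a, b), oracle_count_spikes(st, ev, a, b))
  }
})

test_that("a strong cue response is detected as an increase", {
  b <- planted_cohort(n_units = 1, frac_responsive = 1, gain_hz = 10,
                      baseline_hz = 5, seed = 61)
  res <- detect_responses(b, events = "cue_onset", trial_types = "HR")
  expect_true(res$responsive)
  expect_equal(res$direction, "increase")
  expect_lt(res$p_value, 1e-4)
})

test_that("a suppressed response is detected as a decrease", {
  # alpha-shaped suppression is awkward to plant; instead put the extra rate
  # in the baseline window so the event window sits below it
  bcfg <- behavior_config(n_days = 1, trials_per_day = 60, gamma = 1,
                          lambda = 1, omission_prob = 0, seed = 62)
  kern <- rate_kernel("cue_onset", 12, onset_ms = -1500, duration_ms = 1000)
  b <- generate_cohort(bcfg, list(unit_config("MSN", baseline_rate_hz = 4,
                                              kernels = kern,
                                              dead_time_ms = 0)), seed = 62)
  res <- detect_responses(b, events = "cue_onset", trial_types = "HR")
  expect_true(res$responsive)
  expect_equal(res$direction, "decrease")
})

test_that("units with fewer than three trials of a type are skipped", {
  b <- planted_cohort(n_units = 1, frac_responsive = 1, trials_per_day = 60,
                      seed = 63)
  typed <- classify_trials(b$trials)
  hr <- dplyr::filter(typed, trial_type == "HR")[1:2, ]
  res <- detect_event_related(unit_spikes(b, "u0001"), hr, "cue_onset")
  expect_true(res$skipped)
  expect_false(res$responsive)
})

test_that("detection is invariant to translating the whole recording", {
  b <- planted_cohort(n_units = 1, frac_responsive = 1, seed = 64)
  typed <- classify_trials(b$trials)
  hr <- dplyr::filter(typed, !is.na(trial_type), trial_type == "HR")
  st <- unit_spikes(b, "u0001")
  r1 <- detect_event_related(st, hr, "cue_onset")
  shift <- 123.456
  hr2 <- dplyr::mutate(hr, dplyr::across(dplyr::ends_with("_s"), ~ .x + shift))
  r2 <- detect_event_related(st + shift, hr2, "cue_onset")
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$direction, r2$direction)
})

test_that("null units are flagged at roughly the nominal rate", {
  # modest-n sanity check; the full calibration lives in the acceptance suite
  bcfg <- behavior_config(n_days = 1, trials_per_day = 60, gamma = 1,
                          lambda = 1, omission_prob = 0, seed = 65)
  ucfgs <- lapply(1:300, function(i) unit_config("MSN", baseline_rate_hz = 5,
                                                 dead_time_ms = 0))
  b <- generate_cohort(bcfg, ucfgs, seed = 65)
  res <- detect_responses(b, events = "cue_onset", trial_types = "HR")
  expect_lt(mean(res$responsive), 0.04)
})

test_that("the PSTH conserves spike counts and recovers a constant rate", {
  b <- planted_cohort(n_units = 1, frac_responsive = 0, baseline_hz = 10,
                      seed = 66)
  typed <- classify_trials(b$trials)
  hr <- dplyr::filter(typed, !is.na(trial_type), trial_type == "HR")
  st <- unit_spikes(b, "u0001")
  p <- psth(st, hr$cue_time_s, span_ms = c(-1000, 1000))
  # constant-rate train: every bin near 10 Hz
  expect_equal(mean(p$rate_hz), 10, tolerance = 0.1)
  # conservation: mean rate x span = mean per-trial count in the span
  counts <- count_spikes(st, hr$cue_time_s, -1, 1)
  expect_equal(mean(p$rate_hz) * 2, mean(counts), tolerance = 1e-10)

  # single spike at the alignment time of a single trial
  p1 <- psth(2.0, 2.0, span_ms = c(0, 1000))
  expect_equal(p1$rate_hz[1], 20)  # 1 spike / 0.05 s
  expect_equal(sum(p1$rate_hz[-1]), 0)
})

test_that("sustained activity counts 50-ms bins above baseline + 3 s.d.", {
  # at-baseline unit: few or no bins above the criterion
  b0 <- planted_cohort(n_units = 1, frac_responsive = 0, baseline_hz = 8,
                       seed = 67)
  typed <- classify_trials(b0$trials)
  hr <- dplyr::filter(typed, !is.na(trial_type), trial_type == "HR",
                      outcome == "correct")
  m0 <- sustained_metrics(unit_spikes(b0, "u0001"), hr)
  expect_lte(m0$n_bins_above, 5)
  expect_equal(m0$mean_rate_hz, 8, tolerance = 0.2)

  # strong sustained excess after the first lick: all 100 bins above
  bcfg <- behavior_config(n_days = 1, trials_per_day = 60, gamma = 1,
                          lambda = 1, omission_prob = 0, seed = 68)
  kern <- rate_kernel("first_licking", 60, 0, 5000)
  b1 <- generate_cohort(bcfg, list(unit_config("MSN", baseline_rate_hz = 3,
                                               kernels = kern,
                                               dead_time_ms = 0)), seed = 68)
  typed1 <- classify_trials(b1$trials)
  hr1 <- dplyr::filter(typed1, !is.na(trial_type), trial_type == "HR")
  m1 <- sustained_metrics(unit_spikes(b1, "u0001"), hr1)
  expect_equal(m1$n_bins_above, 100L)
})

test_that("spike-lick correlation follows the removal and significance rules", {
  # perfectly proportional counts give r = 1
  withr::local_seed(99)
  st <- sort(runif(200, 0, 100))
  trials <- tibble::tibble(first_lick_time_s = seq(5, 85, by = 10),
                           cue_time_s = seq(5, 85, by = 10) - 5)
  spk <- count_spikes(st, trials$first_lick_time_s, 0, 5)
  # build licks as two per spike inside each window
  licks <- sort(c(st, st + 1e-4))
  keep <- spk > 0
  r <- spike_lick_correlation(st, licks, trials)
  expect_true(r$defined)
  expect_equal(r$r, 1.0, tolerance = 1e-9)
  expect_equal(r$n_trials_used, sum(keep))

  # zero-spike trials are removed before the correlation
  st2 <- c(10.1, 10.2, 20.1, 20.2, 20.3, 30.5)
  tr2 <- tibble::tibble(first_lick_time_s = c(10, 20, 30, 40, 50),
                        cue_time_s = c(5, 15, 25, 35, 45))
  r2 <- spike_lick_correlation(st2, sort(runif(100, 0, 60)), tr2)
  expect_equal(r2$n_trials_used, 3)

  # fewer than three retained trials: undefined marker, no error
  r3 <- spike_lick_correlation(c(10.1), sort(runif(50, 0, 60)), tr2)
  expect_false(r3$defined)
})
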