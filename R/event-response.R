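#' Trial types from cue and press
#'
#' Each completed trial is one of four types crossing the instruction cue
#' with the chosen lever: HR (high tone, right press) and LL (low, left)
#' are correct; HL (high, left) and LR (low, right) are errors. Omissions
#' carry no type.
#'
#' @param trials Trials tibble.
#' @return The tibble with an added `trial_type` column (`NA` for
#'   omissions).
#' @export
classify_trials <- function(trials) {
  trials |>
    mutate(trial_type = dplyr::case_when(
      .data$response == "none" ~ NA_character_,
      .data$cue == "high" & .data$response == "right" ~ "HR",
      .data$cue == "low" & .data$response == "left" ~ "LL",
      .data$cue == "high" & .data$response == "left" ~ "HL",
      .data$cue == "low" & .data$response == "right" ~ "LR"
    ))
}

#' Peri-event analysis windows
#'
#' Default windows (ms relative to the event): cue onset `[0, +1000)`,
#' choice response `[-700, +300)`, reward sound `[-300, +300)`, first
#' licking `[0, +1000)`. Baselines are taken relative to cue onset and
#' length-matched to the event window: `[-1500, -500)` for the 1000-ms
#' windows and `[-1100, -500)` for the 600-ms reward-sound window.
#'
#' @return Tibble: `event`, `win_start_ms`, `win_end_ms`, `bl_start_ms`,
#'   `bl_end_ms` (baseline relative to cue onset).
#' @export
event_windows <- function() {
  tibble(
    event = c("cue_onset", "choice_response", "reward_sound", "first_licking"),
    win_start_ms = c(0, -700, -300, 0),
    win_end_ms = c(1000, 300, 300, 1000),
    bl_start_ms = c(-1500, -1500, -1100, -1500),
    bl_end_ms = c(-500, -500, -500, -500)
  )
}

.event_time_col <- c(
  cue_onset = "cue_time_s", choice_response = "press_time_s",
  reward_sound = "reward_sound_time_s", first_licking = "first_lick_time_s"
)

#' Spike counts in a window around event times
#'
#' Counts spikes in the half-open interval
#' `[event + start, event + end)` for each event time.
#'
#' @param spike_times Sorted spike times (s).
#' @param event_times Event times (s), one per trial.
#' @param win_start_s,win_end_s Window relative to the event (s).
#' @return Integer vector of per-trial counts.
#' @export
count_spikes <- function(spike_times, event_times, win_start_s, win_end_s) {
  stopifnot(win_end_s > win_start_s)
  # findInterval(x, t, left.open = TRUE) counts spikes strictly before x,
  # so the difference counts spikes in the half-open window [start, end)
  lo <- findInterval(event_times + win_start_s, spike_times, left.open = TRUE)
  hi <- findInterval(event_times + win_end_s, spike_times, left.open = TRUE)
  as.integer(hi - lo)
}

#' Detect event-related activity of one unit for one trial type
#'
#' Compares trial-by-trial spike counts between a pre-cue baseline window
#' and a peri-event window with the two-sample Wilcoxon rank-sum
#' (Mann-Whitney) test. Counts are converted to rates (Hz) so windows of
#' different lengths are comparable; significance at `p < alpha` (default
#' 0.01); direction is the sign of the median event-rate minus
#' median baseline-rate difference. Units with fewer than `min_trials`
#' (default 3) trials of the type are skipped, not errored.
#'
#' @param spike_times Sorted spike times (s) of the unit.
#' @param trials Trials tibble (with `trial_type` from [classify_trials()])
#'   already filtered to one session and one trial type.
#' @param event One of `"cue_onset"`, `"choice_response"`,
#'   `"reward_sound"`, `"first_licking"`.
#' @param windows Window table, see [event_windows()].
#' @param alpha Significance level (default 0.01).
#' @param min_trials Minimum trials required (default 3).
#' @param recording_span Optional `c(start, end)` of the recording (s);
#'   trials whose baseline or event window would extend outside it are
#'   dropped (a truncated window would bias its count toward zero).
#' @return One-row tibble: `event`, `n_trials`, `p_value`, `direction`
#'   (`"increase"`/`"decrease"`/`"none"`), `responsive`, `skipped`, and
#'   list-columns `baseline_counts`, `event_counts`.
#' @export
detect_event_related <- function(spike_times, trials, event,
                                 windows = event_windows(), alpha = 0.01,
                                 min_trials = 3, recording_span = NULL) {
  spec <- filter(windows, .data$event == !!event)
  if (nrow(spec) != 1) abort(sprintf("unknown event '%s'", event))
  time_col <- .event_time_col[[event]]
  trials <- filter(trials, !is.na(.data[[time_col]]))
  if (!is.null(recording_span)) {
    trials <- filter(
      trials,
      .data$cue_time_s + spec$bl_start_ms / 1000 >= recording_span[1],
      .data[[time_col]] + spec$win_start_ms / 1000 >= recording_span[1],
      .data[[time_col]] + spec$win_end_ms / 1000 <= recording_span[2],
      .data$cue_time_s + spec$bl_end_ms / 1000 <= recording_span[2]
    )
  }
  skipped_row <- function(n) tibble(
    event = event, n_trials = n, p_value = NA_real_, direction = "none",
    responsive = FALSE, skipped = TRUE,
    baseline_counts = list(integer()), event_counts = list(integer())
  )
  if (nrow(trials) < min_trials) return(skipped_row(nrow(trials)))
  ev_t <- trials[[time_col]]
  bl_t <- trials$cue_time_s
  win_len <- (spec$win_end_ms - spec$win_start_ms) / 1000
  bl_len <- (spec$bl_end_ms - spec$bl_start_ms) / 1000
  ev_counts <- count_spikes(spike_times, ev_t, spec$win_start_ms / 1000,
                            spec$win_end_ms / 1000)
  bl_counts <- count_spikes(spike_times, bl_t, spec$bl_start_ms / 1000,
                            spec$bl_end_ms / 1000)
  ev_rate <- ev_counts / win_len
  bl_rate <- bl_counts / bl_len
  p <- if (all(ev_rate == ev_rate[1]) && all(bl_rate == bl_rate[1]) &&
           ev_rate[1] == bl_rate[1]) {
    1  # identical constant samples: no evidence
  } else {
    suppressWarnings(stats::wilcox.test(ev_rate, bl_rate)$p.value)
  }
  responsive <- is.finite(p) && p < alpha
  direction <- if (!responsive) "none"
    else if (median(ev_rate) >= median(bl_rate)) "increase" else "decrease"
  tibble(
    event = event, n_trials = nrow(trials), p_value = p,
    direction = direction, responsive = responsive, skipped = FALSE,
    baseline_counts = list(bl_counts), event_counts = list(ev_counts)
  )
}

#' Detect event-related units across a bundle
#'
#' Runs [detect_event_related()] for every quality-passing unit, event and
#' trial type.
#'
#' @param bundle A `session_bundle`.
#' @param events Events to test (default all four).
#' @param trial_types Trial types to test (default the two correct types,
#'   the focus of the analysis).
#' @param alpha,min_trials Passed to [detect_event_related()].
#' @param units Optional character vector restricting unit ids.
#' @return Tibble: one row per unit x trial type x event with the
#'   detection fields plus `unit_id`, `region`, `session_day`,
#'   `trial_type`.
#' @export
detect_responses <- function(bundle, events = event_windows()$event,
                             trial_types = c("HR", "LL"), alpha = 0.01,
                             min_trials = 3, units = NULL) {
  trials <- classify_trials(bundle$trials)
  un <- bundle$units
  if (!is.null(units)) un <- filter(un, .data$unit_id %in% units)
  spk <- .spikes_by_unit(bundle)
  purrr::map(seq_len(nrow(un)), function(i) {
    row <- un[i, ]
    st <- spk[[row$unit_id]]
    day_trials <- filter(trials, .data$session_day == row$session_day)
    purrr::map(trial_types, function(tt) {
      tt_trials <- filter(day_trials, !is.na(.data$trial_type),
                          .data$trial_type == tt)
      purrr::map(events, function(ev) {
        detect_event_related(st, tt_trials, ev, alpha = alpha,
                             min_trials = min_trials,
                             recording_span = c(row$recording_start_s,
                                                row$recording_end_s)) |>
          mutate(unit_id = row$unit_id, region = row$region,
                 session_day = row$session_day, trial_type = tt,
                 .before = 1)
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
}

#' Peri-event time histogram
#'
#' Trial-averaged firing rate in fixed-width bins (default 50 ms) around an
#' alignment event, with the standard error across trials.
#'
#' @param spike_times Sorted spike times (s).
#' @param align_times Alignment event times (s), one per trial.
#' @param span_ms Two-vector `c(start, end)` (ms relative to alignment).
#' @param bin_ms Bin width (ms, default 50).
#' @return Tibble: `bin_start_ms`, `bin_mid_ms`, `rate_hz`, `sem_hz`.
#' @export
psth <- function(spike_times, align_times, span_ms = c(-1500, 1500),
                 bin_ms = 50) {
  stopifnot(length(align_times) >= 1, span_ms[2] > span_ms[1])
  edges_ms <- seq(span_ms[1], span_ms[2], by = bin_ms)
  n_bins <- length(edges_ms) - 1
  counts <- matrix(0, nrow = length(align_times), ncol = n_bins)
  for (k in seq_len(n_bins)) {
    counts[, k] <- count_spikes(spike_times, align_times,
                                edges_ms[k] / 1000, edges_ms[k + 1] / 1000)
  }
  rates <- counts / (bin_ms / 1000)
  tibble(
    bin_start_ms = edges_ms[-length(edges_ms)],
    bin_mid_ms = edges_ms[-length(edges_ms)] + bin_ms / 2,
    rate_hz = colMeans(rates),
    sem_hz = apply(rates, 2, sd) / sqrt(nrow(rates))
  )
}

#' Sustained post-reward activity metrics
#'
#' Quantifies persistent firing after reward consumption begins: the mean
#' rate over the 5 s following the first lick, and the number of 50-ms bins
#' of the trial-averaged post-lick PSTH strictly above the baseline mean
#' plus 3 standard deviations. The baseline mean and s.d. are computed
#' across the pooled 50-ms-binned pre-cue baseline rates of the same
#' trials.
#'
#' @param spike_times Sorted spike times (s).
#' @param trials Correct trials of one type with `first_lick_time_s` and
#'   `cue_time_s` present.
#' @param post_s Post-lick span (s, default 5).
#' @param bl_start_ms,bl_end_ms Baseline window relative to cue onset.
#' @param bin_ms Bin width (ms, default 50).
#' @return One-row tibble: `n_trials`, `mean_rate_hz`, `baseline_mean_hz`,
#'   `baseline_sd_hz`, `n_bins_above`, `skipped`.
#' @export
sustained_metrics <- function(spike_times, trials, post_s = 5,
                              bl_start_ms = -1500, bl_end_ms = -500,
                              bin_ms = 50) {
  trials <- filter(trials, !is.na(.data$first_lick_time_s))
  if (nrow(trials) == 0) {
    return(tibble(n_trials = 0L, mean_rate_hz = NA_real_,
                  baseline_mean_hz = NA_real_, baseline_sd_hz = NA_real_,
                  n_bins_above = NA_integer_, skipped = TRUE))
  }
  post <- psth(spike_times, trials$first_lick_time_s,
               span_ms = c(0, post_s * 1000), bin_ms = bin_ms)
  bl <- psth(spike_times, trials$cue_time_s,
             span_ms = c(bl_start_ms, bl_end_ms), bin_ms = bin_ms)
  # pool single-trial baseline bin rates for the s.d., not the trial average
  n_bl_bins <- (bl_end_ms - bl_start_ms) / bin_ms
  bl_counts <- matrix(0, nrow = nrow(trials), ncol = n_bl_bins)
  edges <- seq(bl_start_ms, bl_end_ms, by = bin_ms)
  for (k in seq_len(n_bl_bins)) {
    bl_counts[, k] <- count_spikes(spike_times, trials$cue_time_s,
                                   edges[k] / 1000, edges[k + 1] / 1000)
  }
  bl_rates <- as.vector(bl_counts / (bin_ms / 1000))
  thr <- mean(bl_rates) + 3 * sd(bl_rates)
  total <- count_spikes(spike_times, trials$first_lick_time_s, 0, post_s)
  tibble(
    n_trials = nrow(trials),
    mean_rate_hz = mean(total / post_s),
    baseline_mean_hz = mean(bl_rates),
    baseline_sd_hz = sd(bl_rates),
    n_bins_above = sum(post$rate_hz > thr),
    skipped = FALSE
  )
}

#' Spike-lick correlation after the first lick
#'
#' Pearson correlation between per-trial spike counts and lick counts in
#' the 5 s after the first lick. Trials in which the unit never spiked are
#' removed first; at least 3 retained trials and non-zero variance on both
#' sides are required, otherwise the correlation is marked undefined.
#'
#' @param spike_times Sorted spike times (s).
#' @param lick_times Sorted lick times (s) of the same session.
#' @param trials Trials with `first_lick_time_s` present.
#' @param post_s Window length (s, default 5).
#' @param alpha Significance level (default 0.01).
#' @return One-row tibble: `n_trials_used`, `r`, `p_value`, `significant`,
#'   `defined`.
#' @export
spike_lick_correlation <- function(spike_times, lick_times, trials,
                                   post_s = 5, alpha = 0.01) {
  trials <- filter(trials, !is.na(.data$first_lick_time_s))
  t0 <- trials$first_lick_time_s
  spk <- count_spikes(spike_times, t0, 0, post_s)
  lck <- count_spikes(lick_times, t0, 0, post_s)
  keep <- spk > 0
  spk <- spk[keep]; lck <- lck[keep]
  undefined <- tibble(n_trials_used = length(spk), r = NA_real_,
                      p_value = NA_real_, significant = FALSE,
                      defined = FALSE)
  if (length(spk) < 3 || sd(spk) == 0 || sd(lck) == 0) return(undefined)
  ct <- stats::cor.test(spk, lck, method = "pearson")
  tibble(n_trials_used = length(spk), r = unname(ct$estimate),
         p_value = ct$p.value, significant = ct$p.value < alpha,
         defined = TRUE)
}
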