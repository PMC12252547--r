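#' @importFrom rlang .data abort %||%
#' @importFrom dplyr arrange filter mutate select group_by ungroup summarise
#'   left_join bind_rows n row_number across all_of first lag lead
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median sd quantile runif rpois setNames
NULL

# Timestamps are stored in seconds with 1 microsecond decimal precision;
# all binning downstream uses half-open [start, end) intervals.
.time_digits <- 6L

.cue_levels <- c("high", "low")
.response_levels <- c("right", "left", "none")
.outcome_levels <- c("correct", "error", "omission")
.region_levels <- c("aDLS", "pVLS")

#' Construct a session bundle
#'
#' A session bundle collects everything one analysis run needs: the
#' trial-by-trial behavior of each daily session, lick timestamps, sorted
#' spike times per unit, mean waveform templates, and per-unit cluster
#' quality metrics. All components are plain tibbles so they compose with
#' dplyr verbs; the bundle itself is a named list with class
#' `"session_bundle"`.
#'
#' @param trials Tibble with columns `session_day`, `trial_index`, `cue`
#'   (`"high"`/`"low"`), `cue_time_s`, `lever_insert_time_s`, `response`
#'   (`"right"`/`"left"`/`"none"`), `press_time_s`, `outcome`
#'   (`"correct"`/`"error"`/`"omission"`), `reward_sound_time_s`,
#'   `first_lick_time_s`. Absent event times are `NA`.
#' @param licks Tibble with columns `session_day`, `lick_time_s`.
#' @param spikes Tibble with columns `unit_id`, `spike_time_s`.
#' @param units Tibble with columns `unit_id`, `region` (`"aDLS"`/`"pVLS"`),
#'   `session_day`, `recording_start_s`, `recording_end_s`,
#'   `sampling_rate_hz`, `l_ratio`, `isolation_distance`, `isi_index`.
#' @param waveforms Tibble with columns `unit_id`, `sample_index`,
#'   `amplitude_uv` (mean template, one row per sample).
#' @param metadata Named list of free-form provenance (subject id, task
#'   variant, generator config).
#' @param validate Check all invariants (default `TRUE`).
#'
#' @return A `session_bundle` object.
#' @export
session_bundle <- function(trials = empty_trials(), licks = empty_licks(),
                           spikes = empty_spikes(), units = empty_units(),
                           waveforms = empty_waveforms(), metadata = list(),
                           validate = TRUE) {
  bundle <- structure(
    list(
      trials = as_tibble(trials), licks = as_tibble(licks),
      spikes = as_tibble(spikes), units = as_tibble(units),
      waveforms = as_tibble(waveforms), metadata = metadata
    ),
    class = "session_bundle"
  )
  if (validate) validate_bundle(bundle)
  bundle
}

#' @export
print.session_bundle <- function(x, ...) {
  cat("<session_bundle>\n")
  cat("  days:  ", length(unique(x$trials$session_day)), "\n")
  cat("  trials:", nrow(x$trials), "\n")
  cat("  licks: ", nrow(x$licks), "\n")
  cat("  units: ", nrow(x$units), "\n")
  cat("  spikes:", nrow(x$spikes), "\n")
  invisible(x)
}

#' @rdname session_bundle
#' @export
empty_trials <- function() {
  tibble(
    session_day = integer(), trial_index = integer(), cue = character(),
    cue_time_s = double(), lever_insert_time_s = double(),
    response = character(), press_time_s = double(), outcome = character(),
    reward_sound_time_s = double(), first_lick_time_s = double()
  )
}

#' @rdname session_bundle
#' @export
empty_licks <- function() tibble(session_day = integer(), lick_time_s = double())

#' @rdname session_bundle
#' @export
empty_spikes <- function() tibble(unit_id = character(), spike_time_s = double())

#' @rdname session_bundle
#' @export
empty_units <- function() {
  tibble(
    unit_id = character(), region = character(), session_day = integer(),
    recording_start_s = double(), recording_end_s = double(),
    sampling_rate_hz = double(), l_ratio = double(),
    isolation_distance = double(), isi_index = double()
  )
}

#' @rdname session_bundle
#' @export
empty_waveforms <- function() {
  tibble(unit_id = character(), sample_index = integer(), amplitude_uv = double())
}

.fail_validation <- function(rule, where) {
  abort(sprintf("validation error: %s (%s)", rule, where),
        class = "striatlearn_validation_error")
}

.check_enum <- function(values, levels, field) {
  bad <- which(!is.na(values) & !(values %in% levels))
  if (length(bad) > 0) {
    abort(sprintf("schema error: unknown value '%s' in %s (row %d)",
                  values[bad[1]], field, bad[1]),
          class = "striatlearn_schema_error")
  }
  invisible(TRUE)
}

#' Validate a session bundle
#'
#' Enforces the trial, lick and unit invariants: outcome logic (correct iff
#' cue/press agree, omission iff no press), event ordering
#' `cue < lever insert <= press <= reward sound <= first lick`, reward sound
#' only on correct trials, strictly increasing trial indices, sorted spike
#' times inside the recording span, and that every unit's `session_day`
#' exists in the behavior table.
#'
#' @param bundle A `session_bundle`.
#' @return The bundle, invisibly; aborts with a classed error naming the
#'   offending row and rule otherwise.
#' @export
validate_bundle <- function(bundle) {
  tr <- bundle$trials
  .check_enum(tr$cue, .cue_levels, "trials.cue")
  .check_enum(tr$response, .response_levels, "trials.response")
  .check_enum(tr$outcome, .outcome_levels, "trials.outcome")
  .check_enum(bundle$units$region, .region_levels, "units.region")

  if (nrow(tr) > 0) {
    for (i in seq_len(nrow(tr))) {
      row <- tr[i, ]
      where <- sprintf("trials row %d (day %s, trial %s)", i,
                       row$session_day, row$trial_index)
      expect_correct <- (row$cue == "high" && row$response == "right") ||
        (row$cue == "low" && row$response == "left")
      if (row$response == "none") {
        if (row$outcome != "omission")
          .fail_validation("response 'none' must be an omission", where)
        if (!is.na(row$press_time_s))
          .fail_validation("omission trial must not carry a press time", where)
      } else {
        if (row$outcome == "omission")
          .fail_validation("omission outcome requires response 'none'", where)
        if (is.na(row$press_time_s))
          .fail_validation("completed trial requires a press time", where)
        if (expect_correct != (row$outcome == "correct"))
          .fail_validation("outcome inconsistent with cue/response mapping", where)
      }
      if (row$outcome == "correct" && is.na(row$reward_sound_time_s))
        .fail_validation("correct trial requires a reward sound time", where)
      if (row$outcome != "correct" && !is.na(row$reward_sound_time_s))
        .fail_validation("reward sound time only on correct trials", where)
      times <- c(row$cue_time_s, row$lever_insert_time_s, row$press_time_s,
                 row$reward_sound_time_s, row$first_lick_time_s)
      times <- times[!is.na(times)]
      if (length(times) >= 2 && any(diff(times) < 0))
        .fail_validation("event times out of order", where)
      if (!is.na(row$cue_time_s) && !is.na(row$lever_insert_time_s) &&
          row$lever_insert_time_s <= row$cue_time_s)
        .fail_validation("lever insertion must follow the cue", where)
    }
    idx_ok <- tr |>
      group_by(.data$session_day) |>
      summarise(ok = !anyDuplicated(.data$trial_index))
    if (!all(idx_ok$ok))
      .fail_validation("trial_index must be unique within a day",
                       sprintf("day %s", idx_ok$session_day[!idx_ok$ok][1]))
  }

  un <- bundle$units
  if (nrow(un) > 0) {
    spk <- .spikes_by_unit(bundle)
    for (i in seq_len(nrow(un))) {
      row <- un[i, ]
      where <- sprintf("units row %d (%s)", i, row$unit_id)
      if (row$recording_end_s <= row$recording_start_s)
        .fail_validation("recording_end must exceed recording_start", where)
      if (row$sampling_rate_hz <= 0)
        .fail_validation("sampling rate must be positive", where)
      if (nrow(bundle$trials) > 0 &&
          !(row$session_day %in% bundle$trials$session_day))
        .fail_validation("unit session_day absent from behavior table", where)
      st <- spk[[row$unit_id]]
      if (length(st) > 0) {
        if (is.unsorted(st))
          .fail_validation("spike times must be sorted", where)
        if (st[1] < row$recording_start_s || st[length(st)] > row$recording_end_s)
          .fail_validation("spike times outside recording span", where)
      }
    }
  }
  invisible(bundle)
}

.trial_cols <- list(
  session_day = readr::col_integer(), trial_index = readr::col_integer(),
  cue = readr::col_character(), cue_time_s = readr::col_double(),
  lever_insert_time_s = readr::col_double(), response = readr::col_character(),
  press_time_s = readr::col_double(), outcome = readr::col_character(),
  reward_sound_time_s = readr::col_double(),
  first_lick_time_s = readr::col_double()
)

#' Read a session bundle from a directory of TSV tables
#'
#' Expects `trials.tsv`, `licks.tsv`, `spikes.tsv`, `units.tsv` and
#' `waveforms.tsv` in `path` (tab-separated, headers as documented in
#' [session_bundle()], empty cell = absent). All invariants are enforced on
#' read.
#'
#' @param path Directory containing the five tables.
#' @return A validated `session_bundle`.
#' @export
read_bundle <- function(path) {
  tables <- c("trials", "licks", "spikes", "units", "waveforms")
  files <- file.path(path, paste0(tables, ".tsv"))
  missing <- tables[!file.exists(files)]
  if (length(missing) > 0) {
    abort(sprintf("missing table: %s", paste0(missing[1], ".tsv")),
          class = "striatlearn_missing_table")
  }
  rd <- function(file, col_types) {
    readr::read_tsv(file, col_types = do.call(readr::cols, col_types),
                    progress = FALSE, na = "")
  }
  bundle <- session_bundle(
    trials = rd(files[1], .trial_cols),
    licks = rd(files[2], list(session_day = readr::col_integer(),
                              lick_time_s = readr::col_double())),
    spikes = rd(files[3], list(unit_id = readr::col_character(),
                               spike_time_s = readr::col_double())),
    units = rd(files[4], list(
      unit_id = readr::col_character(), region = readr::col_character(),
      session_day = readr::col_integer(), recording_start_s = readr::col_double(),
      recording_end_s = readr::col_double(), sampling_rate_hz = readr::col_double(),
      l_ratio = readr::col_double(), isolation_distance = readr::col_double(),
      isi_index = readr::col_double()
    )),
    waveforms = rd(files[5], list(unit_id = readr::col_character(),
                                  sample_index = readr::col_integer(),
                                  amplitude_uv = readr::col_double()))
  )
  bundle
}

.format_time <- function(x) {
  out <- sprintf(paste0("%.", .time_digits, "f"), x)
  out[is.na(x)] <- NA_character_
  out
}

#' Write a session bundle to a directory of TSV tables
#'
#' Emits the five tables with deterministic row order (trials by day then
#' trial index; licks by day then time; spikes by unit then time; units and
#' waveforms by unit id). Timestamps are written with microsecond precision,
#' so `read_bundle(write_bundle(b))` round-trips exactly for times on the
#' microsecond grid.
#'
#' @param bundle A valid `session_bundle`.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  validate_bundle(bundle)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, file) {
    readr::write_tsv(df, file.path(path, file), na = "", progress = FALSE)
  }
  trials <- bundle$trials |>
    arrange(.data$session_day, .data$trial_index) |>
    mutate(across(dplyr::ends_with("_s"), .format_time))
  wr(trials, "trials.tsv")
  licks <- bundle$licks |>
    arrange(.data$session_day, .data$lick_time_s) |>
    mutate(lick_time_s = .format_time(.data$lick_time_s))
  wr(licks, "licks.tsv")
  spikes <- bundle$spikes |>
    arrange(.data$unit_id, .data$spike_time_s) |>
    mutate(spike_time_s = .format_time(.data$spike_time_s))
  wr(spikes, "spikes.tsv")
  units <- bundle$units |>
    arrange(.data$unit_id) |>
    mutate(across(c("recording_start_s", "recording_end_s"), .format_time))
  wr(units, "units.tsv")
  wr(arrange(bundle$waveforms, .data$unit_id, .data$sample_index),
     "waveforms.tsv")
  invisible(path)
}

#' Spike times of one unit
#'
#' @param bundle A `session_bundle`.
#' @param unit_id Unit identifier.
#' @return Sorted numeric vector of spike times (s).
#' @export
unit_spikes <- function(bundle, unit_id) {
  bundle$spikes$spike_time_s[bundle$spikes$unit_id == unit_id]
}

# one-pass split of the spike table; named list keyed by unit_id
.spikes_by_unit <- function(bundle) {
  out <- split(bundle$spikes$spike_time_s, bundle$spikes$unit_id)
  missing <- setdiff(bundle$units$unit_id, names(out))
  if (length(missing)) {
    out <- c(out, setNames(rep(list(double()), length(missing)), missing))
  }
  out
}
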