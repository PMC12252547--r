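#' Area under the ROC curve for two count samples
#'
#' The probability that a draw from `counts_a` exceeds a draw from
#' `counts_b`, counting ties as one half:
#' `P(X_a > X_b) + 0.5 * P(X_a = X_b)`, equivalently the Mann-Whitney
#' `U / (n_a * n_b)`. 0.5 means no discriminability, 1 complete
#' separation with `a` larger. Computed from midranks, so it is exact
#' under ties and invariant to any strictly increasing transform.
#'
#' @param counts_a,counts_b Non-empty numeric samples (per-trial spike
#'   counts).
#' @return Value in `[0, 1]`.
#' @export
auroc <- function(counts_a, counts_b) {
  na <- length(counts_a); nb <- length(counts_b)
  if (na == 0 || nb == 0) abort("auroc: empty sample")
  r <- rank(c(counts_a, counts_b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  u / (na * nb)
}

.bin_edges_ms <- function(span_ms, bin_ms) seq(span_ms[1], span_ms[2], by = bin_ms)

.per_bin_counts <- function(spike_times, align_times, span_ms, bin_ms) {
  edges <- .bin_edges_ms(span_ms, bin_ms)
  n_bins <- length(edges) - 1
  out <- matrix(0L, nrow = length(align_times), ncol = n_bins)
  for (k in seq_len(n_bins)) {
    out[, k] <- count_spikes(spike_times, align_times, edges[k] / 1000,
                             edges[k + 1] / 1000)
  }
  out
}

#' Bin-by-bin auROC coding profile across units
#'
#' For every unit with at least `min_trials` trials of both types, computes
#' the auROC between per-trial spike counts of the target and comparison
#' trial types in sliding 200-ms bins around an alignment event. Per bin,
#' the across-unit distribution of auROC values is tested against 0.5 with
#' the one-sample Wilcoxon signed-rank test (`p < 0.05`).
#'
#' @param bundle A `session_bundle` (trials are typed internally).
#' @param target_type,other_type Trial types compared (auROC > 0.5 means
#'   higher counts on `target_type` trials).
#' @param align_event Alignment event (see [event_windows()]).
#' @param span_ms Analysis span around the event (default `[-1000, 1000)`).
#' @param bin_ms Bin width (default 200).
#' @param min_trials Minimum trials per type per unit (default 3).
#' @param alpha Per-bin significance level (default 0.05).
#' @param units Optional unit-id filter.
#' @return List with `values` (tibble `unit_id`, `bin_start_ms`, `auroc`)
#'   and `bins` (tibble `bin_start_ms`, `n_units`, `p_value`,
#'   `significant`).
#' @export
auroc_series <- function(bundle, target_type, other_type,
                         align_event = "cue_onset", span_ms = c(-1000, 1000),
                         bin_ms = 200, min_trials = 3, alpha = 0.05,
                         units = NULL) {
  trials <- classify_trials(bundle$trials)
  time_col <- .event_time_col[[align_event]]
  un <- bundle$units
  if (!is.null(units)) un <- filter(un, .data$unit_id %in% units)
  edges <- .bin_edges_ms(span_ms, bin_ms)
  starts <- edges[-length(edges)]
  spk <- .spikes_by_unit(bundle)
  vals <- purrr::map(seq_len(nrow(un)), function(i) {
    row <- un[i, ]
    day_trials <- filter(trials, .data$session_day == row$session_day,
                         !is.na(.data$trial_type), !is.na(.data[[time_col]]))
    ta <- filter(day_trials, .data$trial_type == target_type)[[time_col]]
    tb <- filter(day_trials, .data$trial_type == other_type)[[time_col]]
    # drop trials whose span would be truncated by the recording edges
    ok <- function(tt) tt[tt + span_ms[1] / 1000 >= row$recording_start_s &
                            tt + span_ms[2] / 1000 <= row$recording_end_s]
    ta <- ok(ta); tb <- ok(tb)
    if (length(ta) < min_trials || length(tb) < min_trials) return(NULL)
    st <- spk[[row$unit_id]]
    ca <- .per_bin_counts(st, ta, span_ms, bin_ms)
    cb <- .per_bin_counts(st, tb, span_ms, bin_ms)
    tibble(
      unit_id = row$unit_id, bin_start_ms = starts,
      auroc = vapply(seq_along(starts),
                     function(k) auroc(ca[, k], cb[, k]), numeric(1))
    )
  }) |> purrr::list_rbind()
  if (is.null(vals) || nrow(vals) == 0) {
    return(list(values = tibble(unit_id = character(), bin_start_ms = double(),
                                auroc = double()),
                bins = tibble(bin_start_ms = double(), n_units = integer(),
                              p_value = double(), significant = logical())))
  }
  bins <- vals |>
    group_by(.data$bin_start_ms) |>
    summarise(n_units = n(), p_value = {
      d <- .data$auroc - 0.5
      if (all(d == 0)) 1
      else suppressWarnings(stats::wilcox.test(d)$p.value)
    }) |>
    mutate(significant = is.finite(.data$p_value) & .data$p_value < alpha)
  list(values = vals, bins = bins)
}

#' Per-bin paired firing-rate contrasts against the other trial types
#'
#' For each 50-ms bin around the alignment event, compares each unit's mean
#' firing rate on target-type trials against its mean rate on each other
#' trial type with the paired Wilcoxon signed-rank test across units. A bin
#' is flagged when the target differs significantly from any comparison
#' type. Fewer than `min_units` paired units suppresses the flags (test
#' undefined or hopelessly underpowered).
#'
#' @param bundle A `session_bundle`.
#' @param target_type Target trial type (e.g. `"HR"`).
#' @param other_types Comparison types (default the other three).
#' @param align_event,span_ms,bin_ms Binning around the event.
#' @param min_trials Minimum trials per type per unit (default 3).
#' @param alpha Per-comparison significance level (default 0.05).
#' @param min_units Minimum units required (default 6).
#' @param units Optional unit-id filter.
#' @return Tibble: `bin_start_ms`, `comparison`, `n_units`, `p_value`,
#'   `significant`, plus a `flagged` summary column (any comparison
#'   significant in the bin).
#' @export
per_bin_rate_contrast <- function(bundle, target_type,
                                  other_types = setdiff(c("HR", "LL", "HL", "LR"),
                                                        target_type),
                                  align_event = "choice_response",
                                  span_ms = c(-1000, 1000), bin_ms = 50,
                                  min_trials = 3, alpha = 0.05, min_units = 6,
                                  units = NULL) {
  trials <- classify_trials(bundle$trials)
  time_col <- .event_time_col[[align_event]]
  un <- bundle$units
  if (!is.null(units)) un <- filter(un, .data$unit_id %in% units)
  edges <- .bin_edges_ms(span_ms, bin_ms)
  starts <- edges[-length(edges)]
  # per unit: mean rate per bin per trial type
  spk <- .spikes_by_unit(bundle)
  rates <- purrr::map(seq_len(nrow(un)), function(i) {
    row <- un[i, ]
    day_trials <- filter(trials, .data$session_day == row$session_day,
                         !is.na(.data$trial_type), !is.na(.data[[time_col]]))
    st <- unit_spikes(bundle, row$unit_id)
    purrr::map(c(target_type, other_types), function(tt) {
      tms <- filter(day_trials, .data$trial_type == tt)[[time_col]]
      tms <- tms[tms + span_ms[1] / 1000 >= row$recording_start_s &
                   tms + span_ms[2] / 1000 <= row$recording_end_s]
      if (length(tms) < min_trials) return(NULL)
      cm <- .per_bin_counts(st, tms, span_ms, bin_ms)
      tibble(unit_id = row$unit_id, trial_type = tt, bin_start_ms = starts,
             rate_hz = colMeans(cm) / (bin_ms / 1000))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  out <- purrr::map(other_types, function(ot) {
    purrr::map(starts, function(b) {
      wide <- rates |>
        filter(.data$bin_start_ms == b,
               .data$trial_type %in% c(target_type, ot)) |>
        tidyr::pivot_wider(names_from = "trial_type",
                           values_from = "rate_hz") |>
        filter(!is.na(.data[[target_type]]), !is.na(.data[[ot]]))
      n_units <- nrow(wide)
      if (n_units < min_units) {
        return(tibble(bin_start_ms = b, comparison = ot, n_units = n_units,
                      p_value = NA_real_, significant = FALSE))
      }
      d <- wide[[target_type]] - wide[[ot]]
      p <- if (all(d == 0)) 1
        else suppressWarnings(stats::wilcox.test(d)$p.value)
      tibble(bin_start_ms = b, comparison = ot, n_units = n_units,
             p_value = p, significant = is.finite(p) && p < alpha)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  out |>
    group_by(.data$bin_start_ms) |>
    mutate(flagged = any(.data$significant)) |>
    ungroup()
}

#' Matched-trial resampled proportions of responsive units
#'
#' Equalizes statistical power across learning stages by re-running the
#' event-response detector on a fixed number of randomly selected trials
#' per unit. Units with fewer than `n_trials` trials of the type are
#' removed; for each eligible unit, `n_trials` trials are sampled without
#' replacement and [detect_event_related()] is re-run; the percentage of
#' responsive units among eligible units is recorded. The procedure is
#' repeated `n_repeats` times (default 30), each repeat with its own
#' sub-seed derived from `seed`, giving a distribution of proportions.
#'
#' @param bundle A `session_bundle`.
#' @param event Tested event (see [event_windows()]).
#' @param trial_type Tested trial type.
#' @param n_trials Trials sampled per unit (default 20).
#' @param n_repeats Number of resampling repeats (default 30).
#' @param seed Integer seed; same seed, same output.
#' @param alpha Detection significance level (default 0.01).
#' @param direction Count units responsive in this direction
#'   (`"increase"`, `"decrease"` or `"any"`, default `"increase"`).
#' @param units Optional unit-id filter.
#' @return List with `proportions` (numeric vector of length `n_repeats`,
#'   percent) and `n_eligible_units`. Zero eligible units gives an empty
#'   vector.
#' @export
matched_trial_proportions <- function(bundle, event, trial_type,
                                      n_trials = 20, n_repeats = 30,
                                      seed = 1L, alpha = 0.01,
                                      direction = "increase", units = NULL) {
  trials <- classify_trials(bundle$trials)
  time_col <- .event_time_col[[event]]
  un <- bundle$units
  if (!is.null(units)) un <- filter(un, .data$unit_id %in% units)
  unit_trials <- purrr::map(seq_len(nrow(un)), function(i) {
    row <- un[i, ]
    tt <- filter(trials, .data$session_day == row$session_day,
                 !is.na(.data$trial_type), .data$trial_type == trial_type,
                 !is.na(.data[[time_col]]))
    if (nrow(tt) < n_trials) NULL else list(unit = row, trials = tt)
  })
  unit_trials <- purrr::compact(unit_trials)
  n_eligible <- length(unit_trials)
  if (n_eligible == 0) {
    return(list(proportions = numeric(0), n_eligible_units = 0L))
  }
  spk <- .spikes_by_unit(bundle)
  spike_cache <- lapply(unit_trials, function(x) spk[[x$unit$unit_id]])
  props <- vapply(seq_len(n_repeats), function(rep_i) {
    responsive <- vapply(seq_len(n_eligible), function(ui) {
      # independent, reproducible sub-stream per (repeat, unit)
      sub_seed <- (seed + 1000003 * rep_i + 7919 * ui) %% .Machine$integer.max
      rng <- local({ set.seed(sub_seed); sample.int(nrow(unit_trials[[ui]]$trials), n_trials) })
      res <- detect_event_related(
        spike_cache[[ui]], unit_trials[[ui]]$trials[rng, ], event,
        alpha = alpha,
        recording_span = c(unit_trials[[ui]]$unit$recording_start_s,
                           unit_trials[[ui]]$unit$recording_end_s)
      )
      res$responsive && (direction == "any" || res$direction == direction)
    }, logical(1))
    100 * mean(responsive)
  }, numeric(1))
  list(proportions = props, n_eligible_units = n_eligible)
}

#' Empirical cumulative distribution points
#'
#' Standard right-continuous ECDF: for each distinct value, the fraction of
#' observations at or below it.
#'
#' @param values Non-empty numeric vector.
#' @return Tibble `value`, `cum_prob`, sorted by value, ending at 1.
#' @export
ecdf_points <- function(values) {
  if (length(values) == 0) abort("ecdf: no values")
  v <- sort(unique(values))
  tibble(value = v, cum_prob = vapply(v, function(x) mean(values <= x),
                                      numeric(1)))
}

#' Compare resampled proportion distributions across stages
#'
#' Omnibus Kruskal-Wallis test across the stage distributions followed by
#' pairwise Tukey-Kramer-style comparisons on rank means: pooled ranks,
#' standard error `sqrt(N(N+1)/12 * (1/n_i + 1/n_j))`, and the studentized
#' range distribution for the family-wise adjusted p-value.
#'
#' @param dists Named list of numeric vectors (one per stage), all
#'   non-empty.
#' @param alpha Family-wise significance level (default 0.05).
#' @return List with `omnibus` (tibble `statistic`, `df`, `p_value`) and
#'   `pairwise` (tibble `group1`, `group2`, `rank_mean_diff`, `q`,
#'   `p_adj`, `significant`).
#' @export
compare_stage_proportions <- function(dists, alpha = 0.05) {
  if (length(dists) < 2) abort("need at least two distributions")
  if (any(lengths(dists) == 0)) abort("empty distribution")
  if (is.null(names(dists))) names(dists) <- paste0("group", seq_along(dists))
  values <- unlist(dists, use.names = FALSE)
  groups <- factor(rep(names(dists), lengths(dists)), levels = names(dists))
  kw <- if (length(unique(values)) == 1L) {
    list(statistic = c(`Kruskal-Wallis chi-squared` = 0),
         parameter = c(df = length(dists) - 1), p.value = 1)
  } else {
    stats::kruskal.test(values, groups)
  }
  r <- rank(values)
  n_tot <- length(values)
  k <- length(dists)
  rank_means <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  pairs <- utils::combn(names(dists), 2)
  pairwise <- purrr::map(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    diff <- rank_means[[g1]] - rank_means[[g2]]
    se <- sqrt(n_tot * (n_tot + 1) / 12 * (1 / ns[[g1]] + 1 / ns[[g2]]))
    q <- abs(diff) / (se / sqrt(2))
    p_adj <- stats::ptukey(q, nmeans = k, df = Inf, lower.tail = FALSE)
    tibble(group1 = g1, group2 = g2, rank_mean_diff = diff, q = q,
           p_adj = p_adj, significant = p_adj < alpha)
  }) |> purrr::list_rbind()
  list(
    omnibus = tibble(statistic = unname(kw$statistic),
                     df = unname(kw$parameter), p_value = kw$p.value),
    pairwise = pairwise
  )
}
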