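#' Cluster-quality filter
#'
#' A sorted unit enters analysis only when all three sorter-supplied
#' metrics pass: `l_ratio < 0.05`, `isolation_distance > 15`,
#' `isi_index < 0.2` (strict inequalities; boundary values fail). The
#' metrics are consumed, not computed - they require the sorter's feature
#' space.
#'
#' @param l_ratio,isolation_distance,isi_index Quality metrics (unitless).
#' @return Logical vector.
#' @export
quality_pass <- function(l_ratio, isolation_distance, isi_index) {
  if (anyNA(l_ratio) || anyNA(isolation_distance) || anyNA(isi_index))
    abort("missing quality metric: cannot silently pass a unit")
  l_ratio < 0.05 & isolation_distance > 15 & isi_index < 0.2
}

#' Trough-to-peak duration of a mean waveform
#'
#' Time from the global trough to the subsequent maximum of the mean spike
#' template; wide (> 0.6 ms) waveforms mark the MSN/TAN pool, narrow ones
#' FSIs and UIs.
#'
#' @param amplitude Mean template samples (any amplitude unit).
#' @param sampling_rate_hz Template sampling rate.
#' @return Duration in ms.
#' @export
trough_to_peak <- function(amplitude, sampling_rate_hz) {
  stopifnot(sampling_rate_hz > 0)
  trough <- which.min(amplitude)
  if (trough >= length(amplitude))
    abort("malformed waveform: no samples after the trough")
  after <- amplitude[(trough + 1):length(amplitude)]
  peak <- trough + which.max(after)
  (peak - trough) / sampling_rate_hz * 1000
}

#' Proportion of recording time in long inter-spike intervals
#'
#' Sums ISIs longer than 2 s and divides by the total recording time
#' (`Prop_ISIs>2s`). High values mark units with long quiescent periods
#' (UIs); tonic or fast-spiking units score near 0.
#'
#' @param spike_times Sorted spike times (s).
#' @param recording_duration_s Total recording duration (s), > 0.
#' @param threshold_s ISI threshold (default 2 s).
#' @return Fraction in `[0, 1]`; 0 by convention for fewer than 2 spikes.
#' @export
prop_long_isi <- function(spike_times, recording_duration_s, threshold_s = 2) {
  if (recording_duration_s <= 0) abort("recording duration must be positive")
  if (length(spike_times) < 2) return(0)
  isi <- diff(spike_times)
  sum(isi[isi > threshold_s]) / recording_duration_s
}

#' Spike-train autocorrelogram as conditional firing rate
#'
#' For each lag bin (default 1-ms bins to 900 ms) counts ordered spike
#' pairs with that separation and normalizes by `n_spikes * bin_width`,
#' giving the conditional rate (Hz) of observing a spike at that lag after
#' any spike. The zero-lag self term is excluded; lags fall in half-open
#' bins `((k-1), k]` ms.
#'
#' @param spike_times Sorted spike times (s).
#' @param bin_ms Bin width (ms).
#' @param max_lag_ms Maximum lag (ms).
#' @return Tibble `lag_ms` (bin upper edge), `rate_hz`.
#' @export
autocorrelogram <- function(spike_times, bin_ms = 1, max_lag_ms = 900) {
  n <- length(spike_times)
  if (n < 2) abort("autocorrelogram needs at least 2 spikes")
  max_lag_s <- max_lag_ms / 1000
  n_bins <- ceiling(max_lag_ms / bin_ms)
  counts <- numeric(n_bins)
  # window end index for each spike: last spike within max_lag
  hi <- findInterval(spike_times + max_lag_s, spike_times)
  for (i in seq_len(n - 1)) {
    if (hi[i] <= i) next
    lags <- spike_times[(i + 1):hi[i]] - spike_times[i]
    b <- ceiling(lags * 1000 / bin_ms - 1e-9)  # guard float noise at bin edges
    b <- b[b >= 1 & b <= n_bins]
    if (length(b)) {
      tb <- tabulate(b, nbins = n_bins)
      counts <- counts + tb
    }
  }
  tibble(
    lag_ms = seq_len(n_bins) * bin_ms,
    rate_hz = counts / (n * bin_ms / 1000)
  )
}

#' Post-spike suppression duration
#'
#' Baseline is the mean autocorrelogram rate over the 600-900 ms lags; the
#' suppression is the number of consecutive 1-ms bins, starting at lag
#' 1 ms, whose rate stays strictly below baseline, stopping at the first
#' bin at or above it. Short suppression (< 40 ms) is the TAN signature;
#' MSNs show long suppression.
#'
#' @param acg Autocorrelogram tibble from [autocorrelogram()], covering
#'   lags to 900 ms.
#' @return Suppression duration in ms.
#' @export
post_spike_suppression <- function(acg) {
  stopifnot(all(c("lag_ms", "rate_hz") %in% names(acg)))
  if (max(acg$lag_ms) < 900) abort("autocorrelogram must cover lags to 900 ms")
  baseline <- mean(acg$rate_hz[acg$lag_ms >= 600 & acg$lag_ms <= 900])
  if (baseline == 0) abort("undefined suppression: silent 600-900 ms tail")
  rate <- acg$rate_hz[order(acg$lag_ms)]
  below <- rate < baseline
  first_at <- which(!below)[1]
  if (is.na(first_at)) length(below) else first_at - 1L
}

#' Classify a unit into putative striatal cell types
#'
#' Wide waveforms (trough-to-peak > 0.6 ms) are MSNs or TANs, split by
#' post-spike suppression (< 40 ms is a TAN, otherwise MSN); narrow
#' waveforms are FSIs or UIs, split by the long-ISI proportion (< 0.4 is an
#' FSI, otherwise UI). Boundary values follow the strict inequalities:
#' exactly 0.6 ms falls in the narrow pool, exactly 40 ms is an MSN,
#' exactly 0.4 a UI.
#'
#' @param trough_to_peak_ms Waveform width (ms).
#' @param prop_isi_gt2s Long-ISI proportion (needed for narrow units).
#' @param suppression_ms Post-spike suppression (needed for wide units).
#' @return Character vector in `{"MSN", "FSI", "TAN", "UI"}`.
#' @export
classify_unit <- function(trough_to_peak_ms, prop_isi_gt2s = NA_real_,
                          suppression_ms = NA_real_) {
  n <- length(trough_to_peak_ms)
  prop_isi_gt2s <- rep_len(prop_isi_gt2s, n)
  suppression_ms <- rep_len(suppression_ms, n)
  ifelse(
    trough_to_peak_ms > 0.6,
    ifelse(suppression_ms < 40, "TAN", "MSN"),
    ifelse(prop_isi_gt2s < 0.4, "FSI", "UI")
  )
}

#' Quality-filter and classify every unit of a bundle
#'
#' Computes the three classification metrics per unit (waveform width from
#' the template, `Prop_ISIs>2s` and post-spike suppression from the spike
#' train), applies the quality filter, and labels cell types for passing
#' units.
#'
#' @param bundle A `session_bundle`.
#' @return The units tibble with added columns `trough_to_peak_ms`,
#'   `prop_isi_gt2s`, `suppression_ms`, `qc_pass`, `cell_class` (`NA` for
#'   units failing QC).
#' @export
classify_units <- function(bundle) {
  un <- bundle$units
  if (nrow(un) == 0) {
    return(mutate(un, trough_to_peak_ms = double(), prop_isi_gt2s = double(),
                  suppression_ms = double(), qc_pass = logical(),
                  cell_class = character()))
  }
  spk <- .spikes_by_unit(bundle)
  metrics <- purrr::map(seq_len(nrow(un)), function(i) {
    row <- un[i, ]
    wf <- filter(bundle$waveforms, .data$unit_id == row$unit_id) |>
      arrange(.data$sample_index)
    st <- spk[[row$unit_id]]
    ttp <- if (nrow(wf) >= 2) {
      trough_to_peak(wf$amplitude_uv, row$sampling_rate_hz)
    } else NA_real_
    dur <- row$recording_end_s - row$recording_start_s
    pli <- prop_long_isi(st, dur)
    sup <- if (length(st) >= 2) {
      tryCatch(post_spike_suppression(autocorrelogram(st)),
               error = function(e) NA_real_)
    } else NA_real_
    tibble(trough_to_peak_ms = ttp, prop_isi_gt2s = pli,
           suppression_ms = as.numeric(sup))
  }) |> purrr::list_rbind()
  out <- dplyr::bind_cols(un, metrics) |>
    mutate(qc_pass = quality_pass(.data$l_ratio, .data$isolation_distance,
                                  .data$isi_index))
  out |>
    mutate(cell_class = ifelse(
      .data$qc_pass,
      classify_unit(.data$trough_to_peak_ms, .data$prop_isi_gt2s,
                    .data$suppression_ms),
      NA_character_
    ))
}
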