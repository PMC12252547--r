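#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_step geom_ribbon
#'   geom_col geom_hline geom_vline labs theme_minimal autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot a fitted learning curve
#'
#' Daily success rates with the fitted four-parameter logistic overlaid and
#' the 20%/90% crossing days marked.
#'
#' @param object A `learning_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot learning_fit
#' @export
autoplot.learning_fit <- function(object, ...) {
  grid <- tibble(
    session_day = seq(min(object$data$session_day),
                      max(object$data$session_day), length.out = 200)
  )
  grid$fit <- predict(object, grid$session_day)
  p <- ggplot(object$data, aes(x = .data$session_day, y = .data$success_rate)) +
    geom_point() +
    geom_line(data = grid, aes(y = .data$fit), colour = "steelblue") +
    labs(x = "Session day", y = "Success rate",
         title = "Four-parameter logistic learning curve") +
    theme_minimal()
  if (!object$degenerate) {
    p <- p + geom_vline(xintercept = threshold_crossing_day(object, 0.2),
                        linetype = "dashed", colour = "grey40") +
      geom_vline(xintercept = threshold_crossing_day(object, 0.9),
                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot a peri-event time histogram
#'
#' @param psth_tbl Output of [psth()].
#' @param event_label Axis label for the alignment event.
#' @return A ggplot of mean rate with a s.e.m. ribbon.
#' @export
plot_psth <- function(psth_tbl, event_label = "event") {
  ggplot(psth_tbl, aes(x = .data$bin_mid_ms / 1000, y = .data$rate_hz)) +
    geom_ribbon(aes(ymin = .data$rate_hz - .data$sem_hz,
                    ymax = .data$rate_hz + .data$sem_hz), alpha = 0.25) +
    geom_line() +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "grey40") +
    labs(x = sprintf("Time from %s (s)", event_label),
         y = "Firing rate (Hz)") +
    theme_minimal()
}

#' Plot an auROC coding profile
#'
#' Across-unit median auROC per bin with significant bins highlighted.
#'
#' @param series Output of [auroc_series()].
#' @return A ggplot.
#' @export
plot_auroc_series <- function(series) {
  med <- series$values |>
    group_by(.data$bin_start_ms) |>
    summarise(median_auroc = median(.data$auroc)) |>
    left_join(series$bins, by = "bin_start_ms")
  ggplot(med, aes(x = .data$bin_start_ms / 1000, y = .data$median_auroc)) +
    geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey40") +
    geom_line() +
    geom_point(aes(colour = .data$significant)) +
    labs(x = "Bin start (s from event)", y = "Median auROC",
         colour = "p < 0.05") +
    theme_minimal()
}

#' Plot empirical CDFs of resampled proportions by stage
#'
#' @param dists Named list of proportion vectors (percent), e.g. one per
#'   learning stage.
#' @return A ggplot of step ECDFs.
#' @export
plot_proportion_ecdf <- function(dists) {
  df <- purrr::imap(dists, function(v, nm) {
    mutate(ecdf_points(v), stage = nm)
  }) |> purrr::list_rbind()
  ggplot(df, aes(x = .data$value, y = .data$cum_prob, colour = .data$stage)) +
    geom_step() +
    labs(x = "Responsive units (%)", y = "Cumulative probability") +
    theme_minimal()
}
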