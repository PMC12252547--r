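#' Four-parameter logistic learning curve
#'
#' `f(x) = gamma + (lambda - gamma) / (1 + exp(-beta * (x - alpha)))`,
#' with `alpha` the inflection day, `beta` the slope (1/day), `gamma` the
#' lower and `lambda` the upper asymptote of the success rate.
#'
#' @param x Day (numeric, possibly fractional).
#' @param alpha,beta,gamma,lambda Curve parameters.
#' @return Success-rate values in `[gamma, lambda]`.
#' @export
logistic4 <- function(x, alpha, beta, gamma, lambda) {
  gamma + (lambda - gamma) / (1 + exp(-beta * (x - alpha)))
}

.completed <- function(trials) filter(trials, .data$outcome != "omission")

#' Per-session behavioral metrics
#'
#' Success rate is correct trials divided by completed (non-omission)
#' trials; omission rate is omissions over all trials; response bias is
#' `(n_right - n_left) / (n_right + n_left)` over completed trials (+1 all
#' right, -1 all left); response time is the mean latency from lever
#' insertion to press over completed trials.
#'
#' @param trials Trials tibble for one session (see [session_bundle()]).
#' @return A scalar.
#' @export
success_rate <- function(trials) {
  comp <- .completed(trials)
  if (nrow(comp) == 0) abort("undefined rate: no completed trials")
  mean(comp$outcome == "correct")
}

#' @rdname success_rate
#' @export
omission_rate <- function(trials) {
  if (nrow(trials) == 0) abort("undefined metric: no trials")
  mean(trials$outcome == "omission")
}

#' @rdname success_rate
#' @export
response_bias <- function(trials) {
  comp <- .completed(trials)
  if (nrow(comp) == 0) abort("undefined metric: no completed trials")
  (sum(comp$response == "right") - sum(comp$response == "left")) / nrow(comp)
}

#' @rdname success_rate
#' @export
response_time <- function(trials) {
  comp <- .completed(trials)
  if (nrow(comp) == 0) abort("undefined metric: no completed trials")
  mean(comp$press_time_s - comp$lever_insert_time_s)
}

#' Win-shift-win and lose-shift-lose strategy scores
#'
#' A trial is win-shift-win (WSW) when the previous trial was correct, the
#' cue shifted, the animal pressed the opposite lever, and the current trial
#' is again correct - the signature of stimulus-response control. It is
#' lose-shift-lose (LSL) when the previous trial was an error, the animal
#' shifted to the opposite lever despite the cue shift, and erred again -
#' the signature of response-outcome (press/no-reward) control. Both
#' predicates require the previous and current trials to be completed;
#' trials adjacent to an omission are excluded because "shift" is undefined
#' against a non-response. Proportions divide by the number of completed
#' trials in the session.
#'
#' @param trials Trials tibble for one session, in temporal order.
#' @return One-row tibble: `n_completed`, `n_wsw`, `n_lsl`, `prop_wsw`,
#'   `prop_lsl`.
#' @export
score_strategies <- function(trials) {
  if (nrow(trials) == 0) abort("undefined metric: empty session")
  trials <- arrange(trials, .data$trial_index)
  n_completed <- sum(trials$outcome != "omission")
  if (n_completed == 0) abort("undefined metric: no completed trials")
  cur <- trials[-1, ]
  prev <- trials[-nrow(trials), ]
  eligible <- cur$outcome != "omission" & prev$outcome != "omission"
  shifted <- cur$cue != prev$cue & cur$response != prev$response
  wsw <- eligible & shifted & prev$outcome == "correct" & cur$outcome == "correct"
  lsl <- eligible & shifted & prev$outcome == "error" & cur$outcome == "error"
  tibble(
    n_completed = n_completed, n_wsw = sum(wsw), n_lsl = sum(lsl),
    prop_wsw = sum(wsw) / n_completed, prop_lsl = sum(lsl) / n_completed
  )
}

#' Per-day behavioral summary of a bundle
#'
#' @param trials Trials tibble covering one or more days.
#' @return Tibble with one row per `session_day`: counts, success and
#'   omission rates, response bias and time, strategy proportions.
#' @export
session_metrics <- function(trials) {
  trials |>
    group_by(.data$session_day) |>
    dplyr::group_modify(function(df, key) {
      strat <- score_strategies(mutate(df, session_day = key$session_day))
      tibble(
        n_trials = nrow(df),
        n_completed = strat$n_completed,
        success_rate = success_rate(df),
        omission_rate = omission_rate(df),
        response_bias = response_bias(df),
        response_time_s = response_time(df),
        prop_wsw = strat$prop_wsw,
        prop_lsl = strat$prop_lsl
      )
    }) |>
    ungroup()
}

.rss_4pl <- function(par, day, rate) {
  sum((rate - logistic4(day, par[1], par[2], par[3], par[4]))^2)
}

#' Fit the four-parameter logistic learning curve
#'
#' Bounded nonlinear least squares of daily success rates on day index:
#' `0 <= gamma < lambda <= 1`, `beta > 0`, `alpha` within the observed day
#' range plus a 5-day margin. The objective is multimodal in (alpha, beta),
#' so the fit restarts from a deterministic 3 x 3 grid of (alpha, beta)
#' starts (9 starts) and keeps the best converged solution.
#'
#' @param days Integer day indices (>= 4 points).
#' @param rates Daily success rates in `[0, 1]`.
#' @return An object of class `learning_fit`: parameters, RSS, convergence
#'   and degeneracy flags. Supports [generics::tidy()], [generics::glance()],
#'   `predict()` and `autoplot()`.
#' @export
fit_learning_curve <- function(days, rates) {
  stopifnot(length(days) == length(rates))
  if (length(days) < 4) abort("need at least 4 (day, rate) points")
  if (any(rates < 0 | rates > 1)) abort("rates must lie in [0, 1]")
  degenerate <- length(unique(rates)) == 1L
  lower <- c(min(days) - 5, 1e-3, 0, 0)
  upper <- c(max(days) + 5, 20, 1, 1)
  alpha_starts <- quantile(days, c(0.25, 0.5, 0.75), names = FALSE)
  beta_starts <- c(0.3, 1, 3)
  g0 <- max(min(rates), 0)
  l0 <- min(max(rates), 1)
  if (l0 - g0 < 0.05) { g0 <- max(g0 - 0.05, 0); l0 <- min(l0 + 0.05, 1) }
  best <- NULL
  for (a0 in alpha_starts) {
    for (b0 in beta_starts) {
      fit <- tryCatch(
        stats::optim(c(a0, b0, g0, l0), .rss_4pl, day = days, rate = rates,
                     method = "L-BFGS-B", lower = lower, upper = upper,
                     control = list(maxit = 500, factr = 1e4)),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  }
  if (is.null(best)) abort("learning-curve fit failed from every start")
  par <- best$par
  # enforce gamma <= lambda by swap (optim box alone does not order them)
  if (par[3] > par[4]) par[3:4] <- par[4:3]
  structure(
    list(
      alpha = par[1], beta = par[2], gamma = par[3], lambda = par[4],
      rss = best$value, converged = best$convergence == 0 && !degenerate,
      degenerate = degenerate,
      data = tibble(session_day = days, success_rate = rates)
    ),
    class = "learning_fit"
  )
}

#' @export
print.learning_fit <- function(x, ...) {
  cat("4PL learning curve fit\n")
  cat(sprintf("  alpha (inflection day) %.3f\n  beta (slope 1/day)     %.3f\n",
              x$alpha, x$beta))
  cat(sprintf("  gamma (lower asymptote) %.3f\n  lambda (upper asymptote) %.3f\n",
              x$gamma, x$lambda))
  cat(sprintf("  RSS %.5g; converged: %s%s\n", x$rss, x$converged,
              if (x$degenerate) " (degenerate: flat rates)" else ""))
  invisible(x)
}

#' @export
predict.learning_fit <- function(object, newdata = NULL, ...) {
  days <- if (is.null(newdata)) object$data$session_day else newdata
  logistic4(days, object$alpha, object$beta, object$gamma, object$lambda)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy learning_fit
#' @export
tidy.learning_fit <- function(x, ...) {
  tibble(
    term = c("alpha", "beta", "gamma", "lambda"),
    estimate = c(x$alpha, x$beta, x$gamma, x$lambda)
  )
}

#' @method glance learning_fit
#' @export
glance.learning_fit <- function(x, ...) {
  tibble(
    rss = x$rss, n_days = nrow(x$data), converged = x$converged,
    degenerate = x$degenerate,
    t20_day = if (x$degenerate) NA_integer_ else threshold_crossing_day(x, 0.2),
    t90_day = if (x$degenerate) NA_integer_ else threshold_crossing_day(x, 0.9)
  )
}

#' First day the learning curve reaches a fraction of its total rise
#'
#' Solves `f(t) = gamma + p * (lambda - gamma)` analytically:
#' `t_p = alpha - log((1 - p) / p) / beta`, and returns the first integer
#' day at or above the crossing, `ceiling(t_p)` ("the day the success rate
#' reached" the threshold). `p = 0.5` returns the inflection day.
#'
#' @param fit A `learning_fit`.
#' @param p Fraction of the asymptotic rise, in (0, 1).
#' @return Integer day.
#' @export
threshold_crossing_day <- function(fit, p) {
  stopifnot(p > 0, p < 1)
  if (isTRUE(fit$degenerate)) abort("degenerate fit: crossing day undefined")
  t_p <- fit$alpha - log((1 - p) / p) / fit$beta
  # guard: fit noise must not push an exact-integer crossing to the next day
  as.integer(ceiling(t_p - 1e-6))
}

#' Assign early / middle / late learning stages
#'
#' The middle stage is the three days around the day the fitted curve
#' reaches 20% of its rise (`t20 - 1, t20, t20 + 1`); the late stage is the
#' three days up to and including the 90% day (`t90 - 2, t90 - 1, t90`);
#' the early stage is the three consecutive days immediately preceding the
#' middle stage, clamped at day 1 (and so possibly shorter). For fast
#' learners whose middle and late windows collide, the late stage takes
#' precedence and the middle stage keeps only its non-overlapping days.
#'
#' @param fit A converged `learning_fit`.
#' @param n_days Number of days in the experiment.
#' @return Tibble `session_day`, `stage` (`"early"`/`"middle"`/`"late"`/
#'   `"none"`) with attributes `t20_day`, `t90_day`.
#' @export
assign_stages <- function(fit, n_days) {
  t20 <- threshold_crossing_day(fit, 0.2)
  t90 <- threshold_crossing_day(fit, 0.9)
  if (t90 < t20) abort("inconsistent fit: t90 day precedes t20 day")
  middle <- (t20 - 1):(t20 + 1)
  late <- (t90 - 2):t90
  middle <- setdiff(middle, late)  # fast-learner exception: late wins
  early_end <- min(c(middle, late)) - 1
  early <- seq(max(1, early_end - 2), early_end)
  early <- early[early >= 1 & early <= early_end]
  stage <- rep("none", n_days)
  stage[intersect(early, seq_len(n_days))] <- "early"
  stage[intersect(middle, seq_len(n_days))] <- "middle"
  stage[intersect(late, seq_len(n_days))] <- "late"
  out <- tibble(session_day = seq_len(n_days), stage = stage)
  attr(out, "t20_day") <- t20
  attr(out, "t90_day") <- t90
  out
}
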