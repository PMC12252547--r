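make_trials <- function(cue, response) {
  n <- length(cue)
  outcome <- ifelse(
    response == "none", "omission",
    ifelse((cue == "high" & response == "right") |
             (cue == "low" & response == "left"), "correct", "error")
  )
  cue_time <- (seq_len(n) - 1) * 20
  press <- ifelse(response == "none", NA_real_, cue_time + 4)
  tibble::tibble(
    session_day = 1L, trial_index = seq_len(n), cue = cue,
    cue_time_s = cue_time, lever_insert_time_s = cue_time + 3,
    response = response, press_time_s = press, outcome = outcome,
    reward_sound_time_s = ifelse(outcome == "correct", press + 0.5, NA_real_),
    first_lick_time_s = ifelse(outcome == "correct", press + 0.8, NA_real_)
  )
}

test_that("success, omission, bias and response time follow their definitions", {
  # 10 trials, 2 omissions, 6 correct of the 8 completed
  tr <- make_trials(
    cue = c("high", "high", "low", "low", "high", "low", "high", "low", "high", "low"),
    response = c("right", "right", "left", "left", "right", "left",
                 "left", "right", "none", "none")
  )
  expect_equal(success_rate(tr), 0.75)
  expect_equal(omission_rate(tr), 0.2)

  all_correct <- make_trials(c("high", "low"), c("right", "left"))
  expect_equal(success_rate(all_correct), 1.0)

  balanced <- make_trials(rep(c("high", "low"), each = 4),
                          rep(c("right", "left"), each = 4))
  expect_equal(response_bias(balanced), 0)
  all_right <- make_trials(rep("high", 4), rep("right", 4))
  expect_equal(response_bias(all_right), 1)

  rt <- make_trials(c("high", "low"), c("right", "left"))
  rt$press_time_s <- rt$lever_insert_time_s + 1.2
  rt$reward_sound_time_s <- rt$press_time_s + 0.5
  rt$first_lick_time_s <- rt$press_time_s + 0.8
  expect_equal(response_time(rt), 1.2)

  all_om <- make_trials(c("high", "low"), c("none", "none"))
  expect_error(success_rate(all_om), "undefined")
})

test_that("strategy predicates match their literal definitions on small cases", {
  # correct then shifted correct -> WSW
  wsw <- score_strategies(make_trials(c("high", "low"), c("right", "left")))
  expect_equal(wsw$n_wsw, 1L)
  expect_equal(wsw$prop_wsw, 0.5)
  expect_equal(wsw$n_lsl, 0L)

  # error then shifted error -> LSL
  lsl <- score_strategies(make_trials(c("high", "low"), c("left", "right")))
  expect_equal(lsl$n_lsl, 1L)
  expect_equal(lsl$prop_lsl, 0.5)

  # repeated cue: no shift, no WSW
  none <- score_strategies(make_trials(c("high", "high"), c("right", "right")))
  expect_equal(none$n_wsw, 0L)

  # cue shift without a lever shift: neither strategy
  stay <- score_strategies(make_trials(c("high", "low"), c("right", "right")))
  expect_equal(stay$n_wsw + stay$n_lsl, 0L)

  # omission between two correct shifted trials blocks the predicate
  om <- score_strategies(make_trials(c("high", "low", "low"),
                                     c("right", "none", "left")))
  expect_equal(om$n_wsw, 0L)
})

test_that("strategy scores agree with the brute-force enumerator", {
  withr::local_seed(123)
  for (i in 1:200) {
    tr <- random_session(sample(5:40, 1))
    if (all(tr$outcome == "omission")) next
    got <- score_strategies(tr)
    want <- oracle_strategies(tr)
    expect_equal(got$n_wsw, want$n_wsw)
    expect_equal(got$n_lsl, want$n_lsl)
    expect_equal(got$prop_wsw, want$prop_wsw)
    expect_equal(got$prop_lsl, want$prop_lsl)
  }
})

test_that("strategy scores are invariant to the task's left/right x high/low symmetry", {
  withr::local_seed(7)
  for (i in 1:20) {
    tr <- random_session(30)
    flip <- tr
    flip$cue <- c(high = "low", low = "high")[tr$cue]
    flip$response <- c(right = "left", left = "right", none = "none")[tr$response]
    a <- score_strategies(tr)
    b <- score_strategies(flip)
    expect_equal(a$prop_wsw, b$prop_wsw)
    expect_equal(a$prop_lsl, b$prop_lsl)
  }
})

test_that("noiseless 4PL data are refit to the generating parameters", {
  truth <- c(alpha = 7, beta = 1, gamma = 0.5, lambda = 0.95)
  days <- 1:14
  rates <- logistic4(days, truth["alpha"], truth["beta"], truth["gamma"],
                     truth["lambda"])
  fit <- fit_learning_curve(days, rates)
  expect_true(fit$converged)
  expect_equal(fit$alpha, 7, tolerance = 1e-3)
  expect_equal(fit$beta, 1, tolerance = 1e-3)
  expect_equal(fit$gamma, 0.5, tolerance = 1e-3)
  expect_equal(fit$lambda, 0.95, tolerance = 1e-3)
  # midpoint identity
  expect_equal(logistic4(fit$alpha, fit$alpha, fit$beta, fit$gamma, fit$lambda),
               (fit$gamma + fit$lambda) / 2, tolerance = 1e-6)
})

test_that("tidy and glance expose the fit in broom form", {
  fit <- fit_learning_curve(1:14, logistic4(1:14, 7, 1, 0.5, 0.95))
  td <- generics::tidy(fit)
  expect_equal(td$term, c("alpha", "beta", "gamma", "lambda"))
  gl <- generics::glance(fit)
  expect_equal(gl$t20_day, 6L)
  expect_equal(gl$t90_day, 10L)
  expect_true(gl$converged)
})

test_that("flat success rates give a degenerate fit, not an exception", {
  fit <- fit_learning_curve(1:6, rep(0.7, 6))
  expect_true(fit$degenerate)
  expect_false(fit$converged)
  expect_error(threshold_crossing_day(fit, 0.2), "degenerate")
})

test_that("threshold crossings invert the logistic analytically", {
  fit <- make_fit(alpha = 7, beta = 1)
  expect_equal(threshold_crossing_day(fit, 0.5), 7L)   # inflection
  # t20 = 7 - ln 4 = 5.614 -> day 6; t90 = 7 + ln 9 = 9.197 -> day 10
  expect_equal(threshold_crossing_day(fit, 0.2), 6L)
  expect_equal(threshold_crossing_day(fit, 0.9), 10L)
  # monotone in p
  ps <- seq(0.05, 0.95, by = 0.05)
  days <- vapply(ps, function(p) threshold_crossing_day(fit, p), integer(1))
  expect_true(all(diff(days) >= 0))
})

test_that("stage windows follow the t20/t90 rules", {
  st <- assign_stages(make_fit_with_days(6, 12), n_days = 14)
  expect_equal(st$session_day[st$stage == "early"], 2:4)
  expect_equal(st$session_day[st$stage == "middle"], 5:7)
  expect_equal(st$session_day[st$stage == "late"], 10:12)
  expect_equal(attr(st, "t20_day"), 6L)
  expect_equal(attr(st, "t90_day"), 12L)
})

test_that("the early stage is clamped at day 1", {
  st <- assign_stages(make_fit_with_days(4, 10), n_days = 14)
  expect_equal(st$session_day[st$stage == "middle"], 3:5)
  expect_equal(st$session_day[st$stage == "early"], 1:2)
})

test_that("for fast learners the late stage takes the overlapping day", {
  # t90 = t20 + 2: day t90 - 1 = t20 + 1 belongs to late, not middle
  st <- assign_stages(make_fit_with_days(6, 8), n_days = 14)
  expect_equal(st$session_day[st$stage == "late"], 6:8)
  expect_equal(st$session_day[st$stage == "middle"], 5L)
  expect_true(all(table(st$stage[st$stage != "none"]) <= 3))
})

test_that("an inconsistent fit (t90 before t20) errors", {
  fit <- make_fit(alpha = 7, beta = -1)  # decreasing curve inverts the days
  fit$beta <- -1
  expect_error(assign_stages(fit, 14), "inconsistent")
})
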