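test_that("switch logit evaluates the feedback-contingent model", {
  # all-zero parameters are the pure coin flipper
  expect_equal(switch_logit(choice_params(), 0.3, 1), 0)
  expect_equal(switch_logit(choice_params(), 0.7, -1), 0)
  # ms = 1 is probability matching: logit equals the opponent log-odds
  expect_equal(switch_logit(choice_params(ms = 1), 0.8, 1), log(4))
  # sm = -ms flattens the post-loss propensity entirely
  expect_equal(switch_logit(choice_params(ms = 0.5, sm = -0.5), 0.2, -1), 0)
  # hand-evaluated: log(0.2/0.8)*0.48 - 0.21 - 0.20
  expect_equal(switch_logit(choice_params(0.48, -0.38, 0.21, 0.20), 0.2, 1),
               log(0.25) * 0.48 - 0.41, tolerance = 1e-12)
  expect_equal(round(switch_logit(choice_params(0.48, -0.38, 0.21, 0.20),
                                  0.2, 1), 4), -1.0754)
})

test_that("degenerate opponent rates and feedback codes are rejected", {
  expect_error(switch_logit(choice_params(), 0, 1), "strictly inside")
  expect_error(switch_logit(choice_params(), 1, -1), "strictly inside")
  expect_error(switch_probability(choice_params(), 0.5, 0), "wl")
  expect_error(choice_params(ms = Inf), "finite")
})

test_that("switch probability is the logistic transform with its identities", {
  expect_equal(switch_probability(choice_params(), 0.123, 1), 0.5)
  expect_equal(switch_probability(choice_params(ms = 1), 0.8, 1), 0.8)
  expect_equal(switch_probability(choice_params(ms = 1), 0.35, 1), 0.35)
  # log-odds antisymmetry: with no bias terms, P(p) + P(1-p) = 1
  th <- choice_params(ms = 0.7, sm = -0.4)
  for (p in c(0.2, 0.35, 0.65))
    expect_equal(switch_probability(th, p, 1) + switch_probability(th, 1 - p, 1), 1)
})

test_that("probability equals logistic(logit) across random draws", {
  set.seed(41)
  for (i in 1:500) {
    th <- random_params()
    p <- runif(1, 0.01, 0.99)
    w <- sample(c(-1, 1), 1)
    expect_equal(switch_probability(th, p, w),
                 plogis(switch_logit(th, p, w)), tolerance = 1e-15)
  }
})

test_that("model slopes are monotone and the suppression limit holds", {
  ps <- seq(0.05, 0.95, by = 0.05)
  th <- choice_params(ms = 0.6, sm = -0.2, pe = 0.1, ss = 0.2)
  expect_true(all(diff(switch_probability(th, ps, 1)) > 0))       # ms > 0
  expect_true(all(diff(switch_probability(th, ps, -1)) < 0))      # ms + sm > 0
  # sm = -ms: post-loss probability is flat at logistic(-pe + ss)
  sup <- choice_params(ms = 0.6, sm = -0.6, pe = 0.15, ss = 0.25)
  pl <- switch_probability(sup, ps, -1)
  expect_equal(pl, rep(plogis(-0.15 + 0.25), length(ps)))
})

test_that("predicted condition grids match per-cell evaluation", {
  rates <- c(0.2, 0.35, 0.5, 0.65, 0.8)
  flat <- predict_condition_grid(choice_params(), rates)
  expect_equal(flat$switch_rate, rep(0.5, 10))
  pm <- predict_condition_grid(choice_params(ms = 1), rates)
  expect_equal(pm$switch_rate[pm$wl == 1], rates)
  th <- choice_params(0.48, -0.38, 0.21, 0.20)
  g <- predict_condition_grid(th, rates)
  for (i in seq_len(nrow(g)))
    expect_equal(g$switch_rate[i],
                 switch_probability(th, g$p_os[i], g$wl[i]))
  expect_error(predict_condition_grid(th, numeric(0)), "at least one")
})

test_that("empirical switch frequency matches the analytic probability", {
  set.seed(77)
  for (i in 1:3) {
    th <- random_params()
    p <- runif(1, 0.1, 0.9); w <- sample(c(-1, 1), 1)
    pr <- switch_probability(th, p, w)
    n <- 2e5
    emp <- mean(rbinom(n, 1, pr))
    expect_lt(abs(emp - pr), 4 * sqrt(pr * (1 - pr) / n))
  }
})

test_that("running opponent-rate estimate follows the smoothed prior-carrying rule", {
  # hand trace, events {1, 0, 1}, first block (prior 0.5, smoothing 0.5):
  # t1 (0.5 + 0.5 + 0)/(1 + 1 + 0) = 0.5
  # t2 (0.5 + 0.5 + 1)/(1 + 1 + 1) = 2/3
  # t3 (0.5 + 0.5 + 1)/(1 + 1 + 2) = 0.5
  est <- running_opponent_switch_rate(c(1, 0, 1))
  expect_equal(est, c(0.5, 2 / 3, 0.5))
  # block 2 starts from block 1's final value (0.5 + 0.5 + 2)/(1 + 1 + 3) = 0.6,
  # entering as one pseudo-observation under fresh smoothing:
  # (0.5 + 0.6 + 0)/(1 + 1 + 0) = 0.55
  est2 <- running_opponent_switch_rate(c(1, 0, 1, 1), block = c(1, 1, 1, 2))
  expect_equal(est2[4], 0.55)
  # without carryover every block restarts at 0.5
  est3 <- running_opponent_switch_rate(c(1, 1, 1, 1), block = c(1, 1, 2, 2),
                                       carryover = FALSE)
  expect_equal(est3[3], 0.5)
  # first trial of play is always the uninformative prior
  expect_equal(running_opponent_switch_rate(NA)[1], 0.5)
  expect_identical(running_opponent_switch_rate(numeric(0)), numeric(0))
})

test_that("the running estimate never reaches the boundary", {
  est <- running_opponent_switch_rate(rep(1, 500))
  expect_true(all(est < 1))
  est0 <- running_opponent_switch_rate(rep(0, 500))
  expect_true(all(est0 > 0))
  # NA first-of-block events are ignored as evidence
  est_na <- running_opponent_switch_rate(c(NA, 1, 1), block = c(1, 1, 1))
  expect_equal(est_na[2], 0.5)
})
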