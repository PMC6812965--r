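test_that("condition switch rates match a hand-counted toy log", {
  g <- condition_switch_rates(toy_log())
  # post-win trials are t2, t4, t6, t8 (switches 0, 0, 0, 1);
  # post-loss trials are t3, t5, t7 (switches 1, 1, 0)
  expect_equal(g$switch_rate[g$wl == 1], 1 / 4)
  expect_equal(g$n_trials[g$wl == 1], 4)
  expect_equal(g$switch_rate[g$wl == -1], 2 / 3)
  expect_equal(g$n_trials[g$wl == -1], 3)
})

test_that("memory-free cohorts produce flat half-half condition grids", {
  coh <- small_cohort(n_subjects = 5, seed = 44,
                      param_means = c(0, 0, 0, 0), param_sds = c(0, 0, 0, 0))
  g <- condition_switch_rates(coh$trials)
  expect_equal(nrow(g), 10)
  expect_true(all(abs(g$switch_rate - 0.5) < 4 * sqrt(0.25 / g$n_trials)))
})

test_that("observed cells of a probability matcher track the analytic grid", {
  cfg <- session_config(choice_params(ms = 1),
                        opponent_rates = rep(c(0.2, 0.5, 0.8), 4),
                        error_rate = 0)
  s <- simulate_session(cfg, seed = 19)
  g <- condition_switch_rates(s)
  pred <- switch_probability(choice_params(ms = 1), g$p_os, g$wl)
  expect_true(all(abs(g$switch_rate - pred) <
                    4 * sqrt(pmax(pred * (1 - pred), 0.05) / g$n_trials)))
})

test_that("post-loss label reversal is an involution", {
  p <- runif(20); wl <- sample(c(1, -1), 20, replace = TRUE)
  rev1 <- ifelse(wl == -1, 1 - p, p)
  rev2 <- ifelse(wl == -1, 1 - rev1, rev1)
  expect_equal(rev2, p)
})

test_that("reversed-label slopes separate intact from suppressed models", {
  # symmetric model (sm = 0): post-win and post-loss slopes agree
  sym <- small_cohort(n_subjects = 10, n_reps = 2, seed = 71,
                      param_means = c(0.6, 0, 0.15, 0.2),
                      param_sds = c(0.1, 0, 0.05, 0.05))
  rs <- reversed_label_slopes(sym$trials)
  d <- merge(rs$subject_slopes[rs$subject_slopes$wl == 1, ],
             rs$subject_slopes[rs$subject_slopes$wl == -1, ],
             by = "subject_id")
  expect_lt(abs(t.test(d$slope.x, d$slope.y, paired = TRUE)$statistic), 2.5)
  expect_lt(abs(rs$interaction$t), 2.5)
  # full suppression (sm = -ms): post-loss slope indistinguishable from zero
  sup <- small_cohort(n_subjects = 10, n_reps = 2, seed = 72,
                      param_means = c(0.6, -0.6, 0.15, 0.2),
                      param_sds = c(0, 0, 0.05, 0.05))
  rs2 <- reversed_label_slopes(sup$trials)
  g_loss <- rs2$group[rs2$group$wl == -1, ]
  expect_lt(abs(g_loss$t), 2.5)
  g_win <- rs2$group[rs2$group$wl == 1, ]
  expect_gt(g_win$t, 3)
})

test_that("partial suppression yields a significant win/loss slope interaction", {
  coh <- small_cohort(n_subjects = 12, n_reps = 2, seed = 73)
  rs <- reversed_label_slopes(coh$trials)
  expect_gt(rs$interaction$t, 3)
  expect_gt(rs$interaction$estimate, 0)
  # a single opponent rate cannot define a slope
  one <- coh$trials[coh$trials$opponent_rate == 0.5, ]
  expect_error(reversed_label_slopes(one), "two distinct")
})

test_that("history regression is calibrated and detects the rate signal", {
  coh <- small_cohort(n_subjects = 8, seed = 74)
  hr <- history_regression(coh$trials)
  expect_equal(nrow(hr$coefficients), 16)  # intercept + 15 predictors
  expect_equal(hr$n_rows + hr$n_excluded, nrow(coh$trials))
  # the generating process has no dependence beyond the previous trial
  lagged <- grepl("lag[23]", hr$coefficients$term)
  expect_gt(mean(abs(hr$coefficients$z[lagged]) < 2), 0.7)
  # reversed-label interaction with the opponent-rate predictor is positive
  inter <- hr$coefficients[hr$coefficients$term %in% c("wl:rate", "rate:wl"), ]
  expect_gt(inter$z, 2)
})

test_that("coin-flip choices yield null history coefficients", {
  coh <- small_cohort(n_subjects = 6, seed = 75,
                      param_means = c(0, 0, 0, 0), param_sds = c(0, 0, 0, 0))
  hr <- history_regression(coh$trials, method = "glm")
  slopes <- hr$coefficients[hr$coefficients$term != "(Intercept)", ]
  expect_lt(max(abs(slopes$estimate)), 0.2)
  expect_gt(mean(abs(slopes$z) < 2), 0.8)
})

test_that("the win/loss slope contrast survives RT and error controls", {
  coh <- small_cohort(n_subjects = 12, n_reps = 2, seed = 76)
  sv <- stochasticity_vs_noise(coh$trials)
  wl_row <- sv$coefficients[sv$coefficients$term == "wl", ]
  expect_gt(wl_row$t, 2)          # slopes are steeper after wins
  # without suppression the contrast vanishes
  coh0 <- small_cohort(n_subjects = 12, seed = 77,
                       param_means = c(0.6, 0, 0.15, 0.2),
                       param_sds = c(0.1, 0, 0.05, 0.05))
  sv0 <- stochasticity_vs_noise(coh0$trials)
  expect_lt(abs(sv0$coefficients$t[sv0$coefficients$term == "wl"]), 2.5)
  # missing RT/error columns are a hard error
  bad <- coh$trials; bad$rt_ms <- NA_real_
  expect_error(stochasticity_vs_noise(bad), "rt_ms")
})

test_that("success regression recovers the value of model strength", {
  # two sub-cohorts act as the grouping factor; ms varies widely
  c1 <- small_cohort(n_subjects = 20, seed = 78, param_sds = c(0.3, 0.1, 0.08, 0.08))
  c2 <- small_cohort(n_subjects = 20, seed = 79, param_sds = c(0.3, 0.1, 0.08, 0.08))
  fits <- rbind(cbind(fit_cohort(c1$trials), group = 1),
                cbind(fit_cohort(c2$trials), group = 2))
  sr <- success_regression(fits)
  co <- sr$coefficients
  expect_gt(co$t[co$term == "ms"], 2)      # model strength pays off
  expect_lt(abs(co$t[co$term == "abs_ss"]), 2.5)  # ws bias is neutral here
  # identical parameters across players cannot be regressed on
  const <- fits; const[c("ms", "sm", "pe", "ss")] <- rep(c(0.5, -0.3, 0.1, 0.1),
                                                         each = nrow(const))
  expect_error(success_regression(const), "rank-deficient")
})
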