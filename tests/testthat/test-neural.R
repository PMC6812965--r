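neural_cohort <- function(n_subjects = 6, seed = 50, spec = signal_spec(),
                          beta_scales = 1) {
  cfg <- session_config(opponent_rates = rep(c(0.25, 0.5, 0.75), 4),
                        error_rate = 0.05)
  coh <- simulate_cohort(n_subjects, cfg, seed = seed)
  list(cohort = coh,
       epochs = simulate_cohort_epochs(coh, spec, seed = seed + 1,
                                       beta_scales = beta_scales))
}

test_that("window averaging is an arithmetic mean over the half-open window", {
  times <- seq(-200, 1050, by = 50)
  const <- matrix(3.25, 4, length(times))
  expect_equal(window_average(const, times_ms = times), rep(3.25, 4))
  # linear ramp 0 -> 1 over [300, 700): mean is 0.5 up to half a step
  ramp <- matrix(0, 1, length(times))
  idx <- times >= 300 & times < 700
  ramp[1, idx] <- seq(0, 1, length.out = sum(idx))
  expect_equal(window_average(ramp, times_ms = times)[1], 0.5, tolerance = 0.07)
  # a single-step window returns that sample
  one <- matrix(rnorm(length(times)), 1)
  expect_equal(window_average(one, lo = 500, hi = 550, times_ms = times)[1],
               one[1, which(times == 500)])
  expect_error(window_average(one, lo = 700, hi = 300, times_ms = times),
               "exceed")
  expect_error(window_average(one, lo = 2000, hi = 2100, times_ms = times),
               "no time points")
})

test_that("baselining zeroes the pre-feedback interval per trial", {
  nc <- neural_cohort(n_subjects = 2, seed = 61)
  b <- baseline_epochs(nc$epochs)
  pre <- which(b$times_ms >= -200 & b$times_ms < 0)
  expect_lt(max(abs(rowMeans(b$values[, pre]))), 1e-12)
})

test_that("embedded coefficient time courses are recovered", {
  spec <- signal_spec(noise_sd = 3)
  nc <- neural_cohort(n_subjects = 6, seed = 62, spec = spec)
  tc <- timepoint_context_regression(nc$epochs, standardize = FALSE,
                                     method = "pooled", reverse_labels = FALSE)
  for (pred in c("A", "B", "AB")) {
    truth_w <- spec$beta_win[, pred]
    got <- tc[tc$predictor == pred & tc$wl == 1, ]
    cover <- abs(got$beta - truth_w) < 4 * got$se
    expect_gt(mean(cover), 0.85)
  }
  # post-loss curves: present mid-window, gone at the end of the epoch
  lateA <- tc[tc$predictor == "A" & tc$wl == -1 & tc$time_ms >= 700, ]
  midA <- tc[tc$predictor == "A" & tc$wl == -1 &
               tc$time_ms >= 250 & tc$time_ms < 400, ]
  # reversal flips the sign of the post-loss A coefficient when unreversed
  expect_gt(max(abs(midA$beta)), 3 * stats::median(lateA$se))
  expect_lt(mean(abs(lateA$beta)), mean(abs(midA$beta)) / 2)
})

test_that("standardized two-level curves need two subjects and run clean", {
  nc <- neural_cohort(n_subjects = 3, seed = 63)
  one <- nc$epochs
  keep <- one$design$subject_id == 1
  one$values <- one$values[keep, ]; one$design <- one$design[keep, ]
  expect_error(timepoint_context_regression(one), "2 subjects")
  tc <- timepoint_context_regression(nc$epochs)
  expect_equal(sort(unique(tc$predictor)), c("A", "AB", "B", "C"))
  expect_true(all(is.finite(tc$beta) & is.finite(tc$se)))
})

test_that("doubling the embedded betas doubles unstandardized estimates", {
  spec <- signal_spec(noise_sd = 0.5)
  cfg <- session_config(opponent_rates = rep(c(0.25, 0.5, 0.75), 2),
                        error_rate = 0)
  coh <- simulate_cohort(4, cfg, seed = 64)
  e1 <- simulate_cohort_epochs(coh, spec, seed = 70, beta_scales = 1)
  e2 <- simulate_cohort_epochs(coh, spec, seed = 70, beta_scales = 2)
  t1 <- timepoint_context_regression(e1, standardize = FALSE, method = "pooled",
                                     reverse_labels = FALSE)
  t2 <- timepoint_context_regression(e2, standardize = FALSE, method = "pooled",
                                     reverse_labels = FALSE)
  peak <- t1$wl == 1 & t1$time_ms >= 300 & t1$time_ms < 700 &
    t1$predictor == "A"
  expect_equal(t2$beta[peak], 2 * t1$beta[peak], tolerance = 0.15)
})

test_that("pure-noise epochs give calibrated null coefficient curves", {
  spec <- signal_spec(amplitudes = c(A = 0, B = 0, C = 0, AB = 0),
                      erp_gain = 0)
  ps <- numeric(0)
  for (sd in 81:86) {
    nc <- neural_cohort(n_subjects = 3, seed = sd, spec = spec)
    tc <- timepoint_context_regression(nc$epochs, method = "pooled")
    ps <- c(ps, tc$p)
  }
  fp <- mean(ps < 0.05)
  expect_gt(fp, 0.02); expect_lt(fp, 0.09)
})

test_that("PPI residuals are exactly orthogonal to the context design", {
  nc <- neural_cohort(n_subjects = 4, seed = 65)
  ep <- baseline_epochs(nc$epochs)
  sig <- window_average(ep)
  res <- ppi_analysis(ep)
  expect_s3_class(res, "ppi_result")
  expect_equal(sort(unique(res$term)),
               sort(c("A", "B", "C", "AB", "D", "A:D", "B:D", "C:D", "AB:D")))
  # re-derive the step-1 residual and check orthogonality directly
  d <- ep$design[ep$design$wl == 1 & !is.na(ep$design$switch_next), ]
  X <- scale(as.matrix(d[c("A", "B", "C", "AB")]))
  y <- scale(sig[ep$design$wl == 1 & !is.na(ep$design$switch_next)])[, 1]
  r <- lm.fit(cbind(1, X), y)$residuals
  expect_lt(max(abs(cor(r, X))), 1e-8)
})

test_that("an injected residual-choice modulation is recovered with its sign", {
  ep <- ppi_construction(n_subjects = 6, n_trials = 200, d_by_b = 1, seed = 5)
  res <- ppi_analysis(ep, method = "glm")
  dxb <- res[res$term == "B:D" & res$wl == 1, ]
  expect_gt(dxb$estimate, 0)
  expect_gt(dxb$z, 2)
  # signal with no choice-relevant residual: D terms are null
  ep0 <- ppi_construction(n_subjects = 6, n_trials = 200, d_by_b = 0, seed = 6)
  res0 <- ppi_analysis(ep0, method = "glm")
  dterms <- res0[grepl("D", res0$term) & res0$wl == 1, ]
  expect_true(all(abs(dterms$z) < 3.5))
})

test_that("individual-difference correlations detect a constructed coupling", {
  # subjects with stronger model-based behaviour carry stronger signal betas
  cfg <- session_config(opponent_rates = rep(c(0.25, 0.5, 0.75), 4),
                        error_rate = 0.05)
  coh <- simulate_cohort(14, cfg, param_sds = c(0.25, 0.05, 0.05, 0.05),
                         seed = 66)
  scales <- pmax(0, coh$subjects$ms)   # amplitude tied to model strength
  ep <- simulate_cohort_epochs(coh, signal_spec(noise_sd = 2), seed = 67,
                               beta_scales = scales)
  sc <- subject_window_coefficients(ep)
  rs <- reversed_label_slopes(coh$trials)
  wr <- data.frame(subject_id = coh$subjects$subject_id,
                   win_rate = tapply(coh$trials$outcome == "win",
                                     coh$trials$subject_id, mean))
  idc <- individual_difference_correlations(sc, rs$subject_slopes, wr)
  rA <- idc$correlations[idc$correlations$predictor == "A" &
                           idc$correlations$measure == "slope" &
                           idc$correlations$wl == 1, ]
  expect_gt(rA$r, 0.3)
  # shuffling subject labels destroys the coupling
  sc_shuf <- sc
  set.seed(1)
  perm <- sample(unique(sc$subject_id))
  sc_shuf$subject_id <- perm[match(sc$subject_id, unique(sc$subject_id))]
  idc0 <- individual_difference_correlations(sc_shuf, rs$subject_slopes, wr)
  rA0 <- idc0$correlations[idc0$correlations$predictor == "A" &
                             idc0$correlations$measure == "slope" &
                             idc0$correlations$wl == 1, ]
  expect_lt(abs(rA0$r), 0.55)
  # identical coefficients across subjects: correlation undefined, flagged NA
  sc_const <- sc; sc_const$coef <- 0.2
  idc_na <- suppressWarnings(
    individual_difference_correlations(sc_const, rs$subject_slopes, wr))
  expect_true(all(is.na(idc_na$correlations$r)))
})
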