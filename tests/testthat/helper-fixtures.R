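# shared fixture builders; everything is generated in code at test time

exp1_params <- choice_params(ms = 0.48, sm = -0.38, pe = 0.21, ss = 0.20)

# a small cohort under the baseline design, scaled down for test speed
small_cohort <- function(n_subjects = 6, n_reps = 1, seed = 1L,
                         param_means = c(ms = 0.48, sm = -0.38,
                                         pe = 0.21, ss = 0.20),
                         param_sds = c(0.15, 0.12, 0.08, 0.08),
                         trials_per_block = 80L, error_rate = 0.05) {
  cfg <- session_config(opponent_rates = rep(c(0.2, 0.35, 0.5, 0.65, 0.8),
                                             2 * n_reps),
                        trials_per_block = trials_per_block,
                        error_rate = error_rate)
  simulate_cohort(n_subjects, cfg, param_means = param_means,
                  param_sds = param_sds, seed = seed)
}

# deterministic 1-block toy log (hand-checkable); rules alternate by design
toy_log <- function() {
  #            t: 1      2      3      4      5      6      7      8
  player <-  c("run", "run", "freeze", "freeze", "run", "run", "run", "freeze")
  opp <-     c("run", "freeze", "freeze", "run", "run", "freeze", "run", "freeze")
  match <- player == opp
  data.frame(block = 1L, trial_in_block = 1:8, role = "fox",
             player_rule = player, opponent_rule = opp,
             player_switch = c(NA, as.integer(player[-1] != player[-8])),
             opponent_switch = c(NA, as.integer(opp[-1] != opp[-8])),
             outcome = ifelse(match, "win", "loss"),
             action_error = 0L,
             rt_ms = 500, opponent_rate = 0.5,
             stringsAsFactors = FALSE)
}

# random parameter draw over a realistic range
random_params <- function() {
  choice_params(stats::runif(1, 0, 1.2), stats::runif(1, -0.8, 0.2),
                stats::runif(1, -0.3, 0.4), stats::runif(1, -0.3, 0.4))
}

# synthetic PPI construction: pure-noise signal whose step-1 residual is
# made to modulate the B -> upcoming-choice pathway with known sign
ppi_construction <- function(n_subjects = 8, n_trials = 250, d_by_b = 1,
                             seed = 1L) {
  set.seed(seed)
  n <- n_subjects * n_trials
  design <- data.frame(subject_id = rep(seq_len(n_subjects), each = n_trials),
                       block = 1L,
                       trial_in_block = rep(seq_len(n_trials) + 1L, n_subjects),
                       A = stats::rnorm(n),
                       B = sample(c(-1, 1), n, replace = TRUE),
                       C = sample(c(-1, 1), n, replace = TRUE),
                       wl = 1)
  design$AB <- design$A * design$B
  times <- seq(-200, 1050, by = 50)
  noise <- matrix(stats::rnorm(n * length(times)), n, length(times))
  win_idx <- times >= 300 & times < 700
  d_true <- scale(rowMeans(noise[, win_idx]))[, 1]
  design$switch_next <- stats::rbinom(n, 1,
                                      stats::plogis(0.4 * design$B +
                                                    d_by_b * d_true * design$B))
  structure(list(values = noise, times_ms = times, design = design,
                 baselined = TRUE),
            class = "epoch_set")
}
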