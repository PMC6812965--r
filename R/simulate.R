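#' Simulated opponent rule sequence
#'
#' A memoryless opponent that switches rules from one trial to the next with
#' a fixed probability, independent of the player. The first rule is drawn
#' uniformly.
#'
#' @param p_os Per-trial switch probability, in (0, 1) (0 and 1 are allowed
#'   here to generate constant / strictly alternating opponents).
#' @param n_trials Number of trials (>= 1).
#' @param rules Two rule labels, default `c("run", "freeze")`.
#' @return Character vector of rules, length `n_trials`.
#' @export
simulate_opponent <- function(p_os, n_trials, rules = c("run", "freeze")) {
  if (n_trials < 1L) stop("`n_trials` must be at least 1", call. = FALSE)
  if (!is.finite(p_os) || p_os < 0 || p_os > 1)
    stop("`p_os` must lie in [0, 1]", call. = FALSE)
  sw <- c(NA, stats::rbinom(n_trials - 1L, 1L, p_os))
  idx <- cumsum(c(sample.int(2L, 1L) - 1L, sw[-1])) %% 2L
  rules[idx + 1L]
}

#' Session configuration for the fox/rabbit simulator
#'
#' Describes one player-session of the rule-selection matching-pennies game:
#' fixed-rate simulated opponents per block, per-block fox/rabbit role, the
#' player's choice parameters, and an independent action-error process.
#' Defaults emulate the baseline design: ten 80-trial blocks crossing five
#' opponent switch rates (20/35/50/65/80%) with the two roles, randomly
#' ordered at simulation time.
#'
#' @param params [choice_params()] governing the player.
#' @param opponent_rates Per-block opponent switch rates. Default: each of
#'   0.2, 0.35, 0.5, 0.65, 0.8 twice.
#' @param roles Per-block player role (`"fox"`/`"rabbit"`) or NULL to pair
#'   each rate once with each role.
#' @param trials_per_block Trials per block (default 80).
#' @param error_rate Probability of an action error per trial (errors always
#'   count as losses). Default 0.05.
#' @param shuffle_blocks Randomly order the (rate x role) blocks (default
#'   TRUE).
#' @param mode `"rule"` for the rule-selection game (run/freeze) or
#'   `"simple"` for the simple-choice variant (up/down; forces
#'   `error_rate = 0`).
#' @param random_feedback Replace outcomes with a fair coin (non-competition
#'   control); errors still force losses.
#' @param rt_meanlog,rt_sdlog Lognormal RT parameters (ms); `rt_meanlog = NA`
#'   suppresses RTs.
#' @return A `session_config` list.
#' @export
session_config <- function(params = choice_params(),
                           opponent_rates = rep(c(0.2, 0.35, 0.5, 0.65, 0.8), 2),
                           roles = NULL,
                           trials_per_block = 80L,
                           error_rate = 0.05,
                           shuffle_blocks = TRUE,
                           mode = c("rule", "simple"),
                           random_feedback = FALSE,
                           rt_meanlog = log(600), rt_sdlog = 0.3) {
  mode <- match.arg(mode)
  if (trials_per_block < 2L) stop("`trials_per_block` must be >= 2",
                                  call. = FALSE)
  if (any(opponent_rates <= 0 | opponent_rates >= 1))
    stop("`opponent_rates` must lie strictly in (0, 1)", call. = FALSE)
  if (mode == "simple") error_rate <- 0
  if (error_rate < 0 || error_rate >= 1)
    stop("`error_rate` must lie in [0, 1)", call. = FALSE)
  n_blocks <- length(opponent_rates)
  if (is.null(roles)) roles <- rep(c("fox", "rabbit"), length.out = n_blocks)
  if (length(roles) != n_blocks)
    stop("`roles` must have one entry per block", call. = FALSE)
  structure(list(params = as_choice_params(params),
                 opponent_rates = opponent_rates, roles = roles,
                 n_blocks = n_blocks, trials_per_block = as.integer(trials_per_block),
                 error_rate = error_rate, shuffle_blocks = shuffle_blocks,
                 mode = mode, random_feedback = random_feedback,
                 rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog),
            class = "session_config")
}

#' Simulate one player-session against fixed-rate opponents
#'
#' Closed-loop simulation: on every trial after the first of a block the
#' player switches rules with probability
#' `switch_probability(params, p_os_block, wl)` where `wl` is the previous
#' trial's feedback (errors count as losses); the first trial of each block
#' is a uniform draw. Action errors are an independent Bernoulli process;
#' error trials keep the intended rule on record (switch indicators are
#' computed from intended rules) but always end in a loss.
#'
#' @param config A [session_config()].
#' @param seed Optional integer seed; identical seeds give identical logs.
#' @return Data frame with one row per trial: `block`, `trial_in_block`,
#'   `role`, `player_rule`, `opponent_rule`, `player_switch`,
#'   `opponent_switch` (NA on first trials), `outcome`, `action_error`,
#'   `rt_ms`, `opponent_rate`.
#' @export
simulate_session <- function(config, seed = NULL) {
  stopifnot(inherits(config, "session_config"))
  if (!is.null(seed)) set.seed(seed)
  rules <- if (config$mode == "simple") c("up", "down") else c("run", "freeze")
  ord <- if (config$shuffle_blocks) sample.int(config$n_blocks)
         else seq_len(config$n_blocks)
  rates <- config$opponent_rates[ord]
  roles <- config$roles[ord]
  nt <- config$trials_per_block
  blocks <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    opp <- simulate_opponent(rates[b], nt, rules)
    opp_switch <- c(NA, as.integer(opp[-1] != opp[-nt]))
    err <- stats::rbinom(nt, 1L, config$error_rate)
    coin <- if (config$random_feedback) stats::rbinom(nt, 1L, 0.5) else NULL
    ## post-win / post-loss switch probabilities are constant within a block
    p_sw <- c(win = switch_probability(config$params, rates[b], 1),
              loss = switch_probability(config$params, rates[b], -1))
    u <- stats::runif(nt)
    player <- character(nt)
    player_switch <- rep(NA_integer_, nt)
    outcome <- character(nt)
    is_fox <- roles[b] == "fox"
    for (t in seq_len(nt)) {
      if (t == 1L) {
        player[t] <- rules[1L + (u[t] < 0.5)]
      } else {
        p <- if (outcome[t - 1L] == "win") p_sw[["win"]] else p_sw[["loss"]]
        sw <- as.integer(u[t] < p)
        player_switch[t] <- sw
        player[t] <- if (sw == 1L) setdiff(rules, player[t - 1L]) else player[t - 1L]
      }
      won <- if (config$random_feedback) coin[t] == 1L
             else (player[t] == opp[t]) == is_fox
      if (err[t] == 1L) won <- FALSE
      outcome[t] <- if (won) "win" else "loss"
    }
    rt <- if (is.na(config$rt_meanlog)) rep(NA_real_, nt)
          else stats::rlnorm(nt, config$rt_meanlog, config$rt_sdlog)
    blocks[[b]] <- data.frame(
      block = b, trial_in_block = seq_len(nt), role = roles[b],
      player_rule = player, opponent_rule = opp,
      player_switch = player_switch, opponent_switch = opp_switch,
      outcome = outcome, action_error = err, rt_ms = rt,
      opponent_rate = rates[b], stringsAsFactors = FALSE)
  }
  do.call(rbind, blocks)
}

#' Simulate a cohort of independent players
#'
#' Draws per-subject choice parameters from independent Gaussians and
#' simulates one session per subject, with per-subject seeds derived
#' deterministically from the master seed. Defaults centre the parameter
#' distribution on the group estimates typical for the baseline
#' simulated-opponent design.
#'
#' @param n_subjects Number of players (>= 1).
#' @param config A [session_config()] template; its `params` entry is
#'   replaced per subject.
#' @param param_means,param_sds Named means / SDs of the Gaussian parameter
#'   distribution over subjects (order ms, sm, pe, ss). `param_sds = 0`
#'   gives identical parameters.
#' @param seed Master integer seed.
#' @return List with `trials` (row-bound sessions with a `subject_id`
#'   column) and `subjects` (data frame of each subject's true parameters
#'   and seed).
#' @export
simulate_cohort <- function(n_subjects, config = session_config(),
                            param_means = c(ms = 0.48, sm = -0.38,
                                            pe = 0.21, ss = 0.20),
                            param_sds = c(ms = 0.15, sm = 0.12,
                                          pe = 0.08, ss = 0.08),
                            seed = 1L) {
  if (n_subjects < 1L) stop("`n_subjects` must be >= 1", call. = FALSE)
  param_sds <- rep_len(param_sds, 4)
  set.seed(seed)
  theta <- matrix(stats::rnorm(4 * n_subjects, rep(param_means, each = n_subjects),
                               rep(param_sds, each = n_subjects)),
                  ncol = 4, dimnames = list(NULL, c("ms", "sm", "pe", "ss")))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  sessions <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    cfg <- config
    cfg$params <- choice_params(theta[i, 1], theta[i, 2], theta[i, 3], theta[i, 4])
    s <- simulate_session(cfg, seed = sub_seeds[i])
    s$subject_id <- i
    sessions[[i]] <- s
  }
  list(trials = do.call(rbind, sessions),
       subjects = data.frame(subject_id = seq_len(n_subjects), theta,
                             seed = sub_seeds))
}

#' Simulate a fox/rabbit dyad of model-governed players
#'
#' Both players follow the four-parameter choice model; since neither
#' opponent has a programmed rate, each player's opponent-rate input is the
#' running average of the partner's observed switches
#' ([running_opponent_switch_rate()] semantics, carried over across blocks).
#' Outcomes are strictly zero-sum: the fox wins exactly when both intended
#' rules match, except that an action error always loses the trial for the
#' erring player (if both players would err on the same trial, one error is
#' kept at random so the zero-sum and error-implies-loss invariants both
#' hold exactly).
#'
#' @param params_fox,params_rabbit [choice_params()] for the two players.
#' @param n_blocks Number of blocks (default 7).
#' @param trials_per_block Trials per block (default 80).
#' @param error_rate Per-player action-error probability.
#' @param seed Optional integer seed.
#' @return List with elements `fox` and `rabbit`, each a session data frame
#'   as from [simulate_session()] (without `opponent_rate`, which is
#'   unobserved in dyads).
#' @export
simulate_dyad <- function(params_fox, params_rabbit, n_blocks = 7L,
                          trials_per_block = 80L, error_rate = 0.05,
                          seed = NULL) {
  pf <- as_choice_params(params_fox)
  pr <- as_choice_params(params_rabbit)
  if (!is.null(seed)) set.seed(seed)
  rules <- c("run", "freeze")
  nt <- trials_per_block
  smoothing <- 0.5
  ## running-average state per player: prior, successes, count (partner's switches)
  st <- list(fox = c(prior = 0.5, s = 0, k = 0),
             rabbit = c(prior = 0.5, s = 0, k = 0))
  est <- function(z) (smoothing + z[["prior"]] + z[["s"]]) /
    (2 * smoothing + 1 + z[["k"]])
  res <- list(fox = vector("list", n_blocks), rabbit = vector("list", n_blocks))
  for (b in seq_len(n_blocks)) {
    st$fox[c("prior", "s", "k")] <- c(est(st$fox), 0, 0)
    st$rabbit[c("prior", "s", "k")] <- c(est(st$rabbit), 0, 0)
    rule_f <- character(nt); rule_r <- character(nt)
    sw_f <- rep(NA_integer_, nt); sw_r <- rep(NA_integer_, nt)
    out_f <- character(nt)
    err_f <- stats::rbinom(nt, 1L, error_rate)
    err_r <- stats::rbinom(nt, 1L, error_rate)
    both <- which(err_f == 1L & err_r == 1L)
    if (length(both)) {
      keep_f <- stats::rbinom(length(both), 1L, 0.5) == 1L
      err_f[both][!keep_f] <- 0L
      err_r[both][keep_f] <- 0L
    }
    for (t in seq_len(nt)) {
      if (t == 1L) {
        rule_f[t] <- rules[sample.int(2L, 1L)]
        rule_r[t] <- rules[sample.int(2L, 1L)]
      } else {
        wl_f <- if (out_f[t - 1L] == "win") 1 else -1
        p_f <- switch_probability(pf, est(st$fox), wl_f)
        p_r <- switch_probability(pr, est(st$rabbit), -wl_f)
        sw_f[t] <- stats::rbinom(1L, 1L, p_f)
        sw_r[t] <- stats::rbinom(1L, 1L, p_r)
        rule_f[t] <- if (sw_f[t] == 1L) setdiff(rules, rule_f[t - 1L]) else rule_f[t - 1L]
        rule_r[t] <- if (sw_r[t] == 1L) setdiff(rules, rule_r[t - 1L]) else rule_r[t - 1L]
        ## each player observes the partner's switch after the trial resolves
        st$fox[c("s", "k")] <- st$fox[c("s", "k")] + c(sw_r[t], 1)
        st$rabbit[c("s", "k")] <- st$rabbit[c("s", "k")] + c(sw_f[t], 1)
      }
      fox_won <- rule_f[t] == rule_r[t]
      if (err_f[t] == 1L) fox_won <- FALSE
      if (err_r[t] == 1L) fox_won <- TRUE
      out_f[t] <- if (fox_won) "win" else "loss"
    }
    mk <- function(role, own, opp, own_sw, opp_sw, own_out, own_err, opp_err) {
      data.frame(block = b, trial_in_block = seq_len(nt), role = role,
                 player_rule = own, opponent_rule = opp,
                 player_switch = own_sw, opponent_switch = opp_sw,
                 outcome = own_out, action_error = own_err,
                 opponent_action_error = opp_err,
                 rt_ms = NA_real_, stringsAsFactors = FALSE)
    }
    res$fox[[b]] <- mk("fox", rule_f, rule_r, sw_f, sw_r, out_f, err_f, err_r)
    res$rabbit[[b]] <- mk("rabbit", rule_r, rule_f, sw_r, sw_f,
                          ifelse(out_f == "win", "loss", "win"), err_r, err_f)
  }
  list(fox = do.call(rbind, res$fox), rabbit = do.call(rbind, res$rabbit))
}

#' Simulate a cohort of dyads
#'
#' @param n_dyads Number of fox/rabbit pairs.
#' @param param_means,param_sds Gaussian parameter distribution over players
#'   (defaults centred on typical dyad-play estimates).
#' @param n_blocks,trials_per_block,error_rate Passed to [simulate_dyad()].
#' @param seed Master seed.
#' @return List with `trials` (all sessions, with `subject_id` and
#'   `dyad_id`) and `subjects` (true parameters per player).
#' @export
simulate_dyad_cohort <- function(n_dyads,
                                 param_means = c(ms = 0.16, sm = -0.14,
                                                 pe = 0.11, ss = 0.31),
                                 param_sds = c(ms = 0.1, sm = 0.1,
                                               pe = 0.08, ss = 0.1),
                                 n_blocks = 7L, trials_per_block = 80L,
                                 error_rate = 0.05, seed = 1L) {
  set.seed(seed)
  n_pl <- 2L * n_dyads
  theta <- matrix(stats::rnorm(4 * n_pl, rep(param_means, each = n_pl),
                               rep(rep_len(param_sds, 4), each = n_pl)),
                  ncol = 4, dimnames = list(NULL, c("ms", "sm", "pe", "ss")))
  dyad_seeds <- sample.int(.Machine$integer.max - 1L, n_dyads)
  trials <- vector("list", n_pl)
  for (d in seq_len(n_dyads)) {
    i_f <- 2L * d - 1L; i_r <- 2L * d
    dy <- simulate_dyad(theta[i_f, ], theta[i_r, ], n_blocks,
                        trials_per_block, error_rate, seed = dyad_seeds[d])
    dy$fox$subject_id <- i_f; dy$fox$dyad_id <- d
    dy$rabbit$subject_id <- i_r; dy$rabbit$dyad_id <- d
    trials[[i_f]] <- dy$fox; trials[[i_r]] <- dy$rabbit
  }
  list(trials = do.call(rbind, trials),
       subjects = data.frame(subject_id = seq_len(n_pl),
                             dyad_id = rep(seq_len(n_dyads), each = 2),
                             role = rep(c("fox", "rabbit"), n_dyads), theta))
}
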