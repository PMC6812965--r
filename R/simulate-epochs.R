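#' Per-trial context design for feedback-locked analyses
#'
#' Builds, for every trial with a defined previous-trial state, the four
#' context variables carried by the feedback-locked signal at that trial:
#'
#' * `A` -- the opponent's overall switch rate (programmed block rate),
#'   z-scored across retained trials;
#' * `B` -- the opponent's switch on this trial (lag-1 relative to the
#'   upcoming choice), effect-coded +1/-1;
#' * `C` -- the player's switch on this trial, effect-coded +1/-1;
#' * `AB` -- the product of `A` and `B` (global x local expectancy);
#'
#' plus `wl` (this trial's feedback, +1/-1), `switch_next` (the player's
#' switch on the following trial, NA at block ends) and `subject_id`.
#' Everything is computable at feedback time of the indexed trial.
#'
#' @param trials Session or cohort log (needs `opponent_rate`); rows with
#'   `trial_in_block == 1` are dropped.
#' @return Data frame with columns `subject_id`, `block`, `trial_in_block`,
#'   `A`, `B`, `C`, `AB`, `wl`, `switch_next`.
#' @export
context_design <- function(trials) {
  if (is.null(trials$subject_id)) trials$subject_id <- 1L
  if (is.null(trials$opponent_rate))
    stop("`trials` needs an `opponent_rate` column (programmed block rate)",
         call. = FALSE)
  ord <- order(trials$subject_id, trials$block, trials$trial_in_block)
  trials <- trials[ord, , drop = FALSE]
  grp <- interaction(trials$subject_id, trials$block, drop = TRUE)
  nxt <- stats::ave(as.numeric(trials$player_switch), grp,
                    FUN = function(x) c(x[-1], NA))
  keep <- trials$trial_in_block > 1 & !is.na(trials$player_switch) &
    !is.na(trials$opponent_switch)
  d <- data.frame(subject_id = trials$subject_id[keep],
                  block = trials$block[keep],
                  trial_in_block = trials$trial_in_block[keep],
                  A = zscore(trials$opponent_rate[keep]),
                  B = 2 * trials$opponent_switch[keep] - 1,
                  C = 2 * trials$player_switch[keep] - 1,
                  wl = ifelse(trials$outcome[keep] == "win", 1, -1),
                  switch_next = nxt[keep])
  d$AB <- d$A * d$B
  d[c("subject_id", "block", "trial_in_block", "A", "B", "C", "AB", "wl",
      "switch_next")]
}

#' Specification of the synthetic feedback-locked signal
#'
#' Defines the generative model for per-trial signal epochs aligned to
#' feedback onset: an event-related baseline waveform per feedback type, a
#' coefficient time course per context variable that is attenuated after
#' losses beyond a latency, plus subject offsets and Gaussian noise.
#'
#' The canonical coefficient time course is zero before 100 ms, ramps up to
#' its amplitude by 300 ms, holds to 700 ms and decays to zero by 1000 ms.
#' After losses the same course is multiplied by an attenuation ramp that
#' falls from 1 at `attenuation_ms` to 0 over 150 ms, emulating information
#' that is initially present but then suppressed.
#'
#' @param times_ms Epoch time grid in ms (feedback onset at 0); must be an
#'   equally spaced increasing grid.
#' @param amplitudes Named coefficient amplitudes for `A`, `B`, `C`, `AB`
#'   (signal units per unit predictor).
#' @param attenuation_ms Latency after which post-loss coefficients are
#'   ramped to zero (default 400 ms).
#' @param loss_gain Multiplier on post-loss amplitudes before the ramp
#'   (1 = identical to post-win until `attenuation_ms`).
#' @param noise_sd Trial-level Gaussian noise SD (default 4, a realistic
#'   single-trial signal-to-noise for feedback-locked scalp potentials).
#' @param subject_sd SD of the per-subject additive offset.
#' @param erp_gain Amplitude of the baseline feedback waveform.
#' @return A `signal_spec` list with evaluated coefficient matrices
#'   `beta_win`, `beta_loss` (time x predictor) and waveforms `erp_win`,
#'   `erp_loss`.
#' @export
signal_spec <- function(times_ms = seq(-200, 1050, by = 50),
                        amplitudes = c(A = 1, B = 0.6, C = 0.3, AB = -0.8),
                        attenuation_ms = 400, loss_gain = 1,
                        noise_sd = 4, subject_sd = 1, erp_gain = 5) {
  if (is.unsorted(times_ms, strictly = TRUE))
    stop("`times_ms` must be strictly increasing", call. = FALSE)
  if (noise_sd <= 0) stop("`noise_sd` must be positive", call. = FALSE)
  stopifnot(all(c("A", "B", "C", "AB") %in% names(amplitudes)))
  t <- times_ms
  ramp <- function(x, lo, hi) pmin(1, pmax(0, (x - lo) / (hi - lo)))
  course <- ramp(t, 100, 300) * (1 - ramp(t, 700, 1000))
  atten <- 1 - ramp(t, attenuation_ms, attenuation_ms + 150)
  beta_win <- outer(course, amplitudes[c("A", "B", "C", "AB")])
  beta_loss <- outer(course * atten, loss_gain * amplitudes[c("A", "B", "C", "AB")])
  colnames(beta_win) <- colnames(beta_loss) <- c("A", "B", "C", "AB")
  bump <- function(mu, sd) exp(-0.5 * ((t - mu) / sd)^2)
  structure(list(times_ms = t,
                 beta_win = beta_win, beta_loss = beta_loss,
                 erp_win = erp_gain * bump(300, 120),
                 erp_loss = erp_gain * (bump(300, 120) - 0.8 * bump(250, 50)),
                 noise_sd = noise_sd, subject_sd = subject_sd,
                 amplitudes = amplitudes, attenuation_ms = attenuation_ms),
            class = "signal_spec")
}

#' Simulate feedback-locked signal epochs for a session
#'
#' Generates one epoch (time course) per retained trial:
#' `y(trial, t) = erp_wl(t) + sum_k beta_k(wl, t) x_k(trial) + subject
#' offset + noise`, with the context variables `x_k` from
#' [context_design()]. The pre-feedback interval carries only noise and the
#' subject offset, so downstream baselining is exercised honestly.
#'
#' @param trials A single-subject session log (with `opponent_rate`).
#' @param spec A [signal_spec()].
#' @param seed Optional integer seed.
#' @param subject_offset Additive offset; default drawn from
#'   `N(0, spec$subject_sd)`.
#' @param beta_scale Scalar multiplier on all embedded coefficients (handle
#'   for linearity and individual-difference constructions).
#' @return An `epoch_set` list: `values` (trials x time matrix),
#'   `times_ms`, `design` (the matching [context_design()] rows).
#' @export
simulate_neural_epochs <- function(trials, spec = signal_spec(), seed = NULL,
                                   subject_offset = NULL, beta_scale = 1) {
  stopifnot(inherits(spec, "signal_spec"))
  if (!is.null(seed)) set.seed(seed)
  design <- context_design(trials)
  n <- nrow(design)
  nt <- length(spec$times_ms)
  if (is.null(subject_offset))
    subject_offset <- stats::rnorm(1, 0, spec$subject_sd)
  X <- as.matrix(design[c("A", "B", "C", "AB")])
  win <- design$wl == 1
  vals <- matrix(stats::rnorm(n * nt, 0, spec$noise_sd), n, nt) + subject_offset
  if (any(win))
    vals[win, ] <- vals[win, , drop = FALSE] +
      rep(spec$erp_win, each = sum(win)) +
      beta_scale * X[win, , drop = FALSE] %*% t(spec$beta_win)
  if (any(!win))
    vals[!win, ] <- vals[!win, , drop = FALSE] +
      rep(spec$erp_loss, each = sum(!win)) +
      beta_scale * X[!win, , drop = FALSE] %*% t(spec$beta_loss)
  structure(list(values = vals, times_ms = spec$times_ms, design = design),
            class = "epoch_set")
}

#' Simulate epochs for a whole cohort
#'
#' Applies [simulate_neural_epochs()] per subject with seeds derived from
#' the master seed, then row-binds values and designs.
#'
#' @param cohort A list as returned by [simulate_cohort()] (uses
#'   `cohort$trials`).
#' @param spec A [signal_spec()].
#' @param seed Master integer seed.
#' @param beta_scales Optional per-subject multiplier on embedded
#'   coefficients (recycled); default 1.
#' @return An `epoch_set` with multi-subject `design`.
#' @export
simulate_cohort_epochs <- function(cohort, spec = signal_spec(), seed = 1L,
                                   beta_scales = 1) {
  trials <- cohort$trials
  ids <- unique(trials$subject_id)
  beta_scales <- rep_len(beta_scales, length(ids))
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, length(ids))
  parts <- lapply(seq_along(ids), function(i) {
    simulate_neural_epochs(trials[trials$subject_id == ids[i], , drop = FALSE],
                           spec, seed = seeds[i], beta_scale = beta_scales[i])
  })
  structure(list(values = do.call(rbind, lapply(parts, `[[`, "values")),
                 times_ms = spec$times_ms,
                 design = do.call(rbind, lapply(parts, `[[`, "design"))),
            class = "epoch_set")
}
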