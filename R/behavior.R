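#' Observed condition-average switch rates
#'
#' Mean player switch rate per (programmed opponent switch rate x previous
#' feedback) cell, the empirical surface the choice model is fitted to.
#' First trials of each block are excluded (no defined feedback or switch);
#' action errors on the previous trial count as losses.
#'
#' @param trials Session or cohort log with `opponent_rate`.
#' @return A `condition_grid` data frame (`p_os`, `wl`, `switch_rate`,
#'   `n_trials`). Cells with no trials are omitted with a warning.
#' @export
condition_switch_rates <- function(trials) {
  mf <- lagged_frame(trials)
  agg <- stats::aggregate(cbind(rate = mf$player_switch) ~ p_os + wl,
                          data = mf, FUN = mean)
  cnt <- stats::aggregate(cbind(n = rep(1, nrow(mf))) ~ p_os + wl,
                          data = mf, FUN = sum)
  grid <- merge(agg, cnt, by = c("p_os", "wl"))
  full <- expand.grid(p_os = unique(mf$p_os), wl = c(1, -1))
  if (nrow(grid) < nrow(full))
    warning(nrow(full) - nrow(grid), " empty condition cell(s) omitted",
            call. = FALSE)
  names(grid) <- c("p_os", "wl", "switch_rate", "n_trials")
  as_condition_grid(grid[order(grid$p_os, -grid$wl), ])
}

## Per-trial frame with previous feedback, excluding first-of-block trials.
lagged_frame <- function(trials) {
  if (is.null(trials$subject_id)) trials$subject_id <- 1L
  if (is.null(trials$opponent_rate))
    stop("`trials` needs an `opponent_rate` column", call. = FALSE)
  ord <- order(trials$subject_id, trials$block, trials$trial_in_block)
  trials <- trials[ord, , drop = FALSE]
  grp <- interaction(trials$subject_id, trials$block, drop = TRUE)
  prev_out <- stats::ave(as.character(trials$outcome), grp,
                         FUN = function(x) c(NA, x[-length(x)]))
  keep <- trials$trial_in_block > 1 & !is.na(trials$player_switch) &
    !is.na(prev_out)
  data.frame(subject_id = trials$subject_id[keep],
             block = trials$block[keep],
             trial_in_block = trials$trial_in_block[keep],
             p_os = trials$opponent_rate[keep],
             wl = ifelse(prev_out[keep] == "win", 1, -1),
             player_switch = as.integer(trials$player_switch[keep]),
             action_error = if (is.null(trials$action_error)) NA_integer_
                            else trials$action_error[keep],
             rt_ms = if (is.null(trials$rt_ms)) NA_real_
                     else trials$rt_ms[keep])
}

#' Per-subject switch-rate slopes with post-loss label reversal
#'
#' Quantifies model-based choice after wins and after losses on a common
#' axis. Per subject and feedback condition, the condition-mean switch rate
#' is regressed (least squares, proportion scale) on the opponent switch
#' rate, after relabelling the post-loss axis (`p` becomes `1 - p`) so that
#' model-conform behaviour has a positive slope in both conditions. The
#' group-level win/loss x opponent-rate interaction is tested in a mixed
#' model over subject-condition cell means with stepwise-simplified random
#' effects; per-condition group slopes come from one-sample t tests over
#' subject slopes.
#'
#' @param trials Cohort log with `subject_id` and `opponent_rate`.
#' @return A `slope_result` list: `subject_slopes` (subject x condition
#'   slopes), `group` (per-condition mean slope, SE, t, df), `interaction`
#'   (estimate, SE, t, df) and `ranef_structure` (the random-effects
#'   formula actually used).
#' @export
reversed_label_slopes <- function(trials) {
  mf <- lagged_frame(trials)
  if (length(unique(mf$p_os)) < 2L)
    stop("slopes need at least two distinct opponent switch rates",
         call. = FALSE)
  cells <- stats::aggregate(player_switch ~ subject_id + p_os + wl, data = mf,
                            FUN = mean)
  names(cells)[4] <- "rate"
  cells$x <- ifelse(cells$wl == 1, cells$p_os, 1 - cells$p_os)

  slopes <- do.call(rbind, lapply(split(cells, cells[c("wl", "subject_id")]),
    function(d) {
      if (length(unique(d$x)) < 2L) return(NULL)
      data.frame(subject_id = d$subject_id[1], wl = d$wl[1],
                 slope = stats::coef(stats::lm(rate ~ x, data = d))[["x"]])
    }))
  rownames(slopes) <- NULL

  grp <- do.call(rbind, lapply(split(slopes, slopes$wl), function(d) {
    tt <- stats::t.test(d$slope)
    data.frame(wl = d$wl[1], slope = mean(d$slope),
               se = stats::sd(d$slope) / sqrt(nrow(d)),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  }))
  rownames(grp) <- NULL

  cells$wlf <- cells$wl  # effect-coded +1/-1
  fit <- fit_lmer_fallback(
    rate ~ x * wlf,
    list("(1 + x * wlf | subject_id)", "(1 + x | subject_id)",
         "(1 | subject_id)"),
    data = cells)
  co <- summary(fit$model)$coefficients
  inter <- co["x:wlf", , drop = TRUE]
  n_sub <- length(unique(cells$subject_id))
  structure(list(subject_slopes = slopes, group = grp,
                 interaction = data.frame(estimate = inter[["Estimate"]],
                                          se = inter[["Std. Error"]],
                                          t = inter[["t value"]],
                                          df = n_sub - 1),
                 ranef_structure = fit$structure),
            class = "slope_result")
}

## Try progressively simpler random-effects structures; return the first fit
## that is neither singular nor flagged by the optimizer, else the simplest
## fit that ran at all (with a logged notice).
fit_lmer_fallback <- function(fixed, ranefs, data, binomial = FALSE) {
  last <- NULL
  for (re in ranefs) {
    f <- stats::as.formula(paste(paste(deparse(fixed), collapse = " "), "+", re))
    m <- tryCatch(suppressMessages(suppressWarnings(
      if (binomial)
        lme4::glmer(f, data = data, family = stats::binomial(), nAGQ = 0L)
      else
        lme4::lmer(f, data = data, REML = FALSE))),
      error = function(e) NULL)
    if (is.null(m)) next
    clean <- !lme4::isSingular(m, tol = 1e-4) &&
      length(m@optinfo$conv$lme4$messages) == 0L
    if (clean) return(list(model = m, structure = re))
    last <- list(model = m, structure = re)
  }
  if (is.null(last)) stop("no random-effects structure converged", call. = FALSE)
  message("falling back to random-effects structure ", last$structure,
          " (singular or flagged fit)")
  last
}

#' Multilevel logistic regression of choices on recent history
#'
#' Predicts the trial-n switch/repeat choice from the opponent's overall
#' switch rate, the opponent's and the player's switch history at lags 1 to
#' `lags`, the previous-trial win/loss contrast, and the interaction of the
#' contrast with every history/context predictor (15 predictors at the
#' default 3 lags). Continuous predictors are z-scored and binary ones
#' effect-coded (+1/-1) within the fitted subset. With
#' `reverse_labels = TRUE` opponent predictors are sign-flipped on post-loss
#' rows, and player predictors are flipped only where separate post-win /
#' post-loss fits show an empirical sign flip, so the interaction terms
#' compare coefficient magnitudes rather than signs.
#'
#' @param trials Cohort log with `subject_id` and `opponent_rate`.
#' @param lags Number of history lags (default 3).
#' @param reverse_labels Apply post-loss label reversal (default TRUE).
#' @param method `"glmer"` (random intercept per subject, per-dyad level
#'   added when a `dyad_id` column is present) or `"glm"` (pooled).
#' @return A `history_result` list: `coefficients` (term, estimate, se, z,
#'   p), `n_rows`, `n_excluded`, `flipped_player_terms`, `method`.
#' @export
history_regression <- function(trials, lags = 3L,
                               reverse_labels = TRUE,
                               method = c("glmer", "glm")) {
  method <- match.arg(method)
  if (is.null(trials$subject_id)) trials$subject_id <- 1L
  ord <- order(trials$subject_id, trials$block, trials$trial_in_block)
  trials <- trials[ord, , drop = FALSE]
  grp <- interaction(trials$subject_id, trials$block, drop = TRUE)
  lag_k <- function(x, k) stats::ave(as.numeric(x), grp,
                                     FUN = function(v) c(rep(NA_real_, k),
                                                         v[seq_len(max(0L, length(v) - k))]))
  d <- data.frame(subject_id = trials$subject_id,
                  y = as.integer(trials$player_switch),
                  rate = trials$opponent_rate)
  if (!is.null(trials$dyad_id)) d$dyad_id <- trials$dyad_id
  prev_out <- stats::ave(as.character(trials$outcome), grp,
                         FUN = function(x) c(NA, x[-length(x)]))
  d$wl <- ifelse(prev_out == "win", 1, -1)
  for (k in seq_len(lags)) {
    d[[paste0("opp_lag", k)]] <- 2 * lag_k(trials$opponent_switch, k) - 1
    d[[paste0("ply_lag", k)]] <- 2 * lag_k(trials$player_switch, k) - 1
  }
  n_before <- nrow(d)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  hist_terms <- c("rate", paste0("opp_lag", seq_len(lags)),
                  paste0("ply_lag", seq_len(lags)))
  d$rate <- zscore(d$rate)

  flipped <- character(0)
  if (reverse_labels) {
    opp_terms <- c("rate", paste0("opp_lag", seq_len(lags)))
    for (v in opp_terms) d[[v]] <- ifelse(d$wl == -1, -d[[v]], d[[v]])
    ## flip player terms only on an empirical post-win/post-loss sign flip
    signs <- sapply(c(1, -1), function(w) {
      sub <- d[d$wl == w, , drop = FALSE]
      f <- stats::as.formula(paste("y ~", paste(hist_terms, collapse = "+")))
      sign(stats::coef(stats::glm(f, data = sub, family = stats::binomial()))[
        paste0("ply_lag", seq_len(lags))])
    })
    flip <- rownames(signs)[signs[, 1] != signs[, 2]]
    for (v in flip) d[[v]] <- ifelse(d$wl == -1, -d[[v]], d[[v]])
    flipped <- flip
  }

  fixed <- paste("y ~ wl +", paste(hist_terms, collapse = " + "), "+",
                 paste(paste0("wl:", hist_terms), collapse = " + "))
  if (method == "glmer") {
    ranef <- if (!is.null(d$dyad_id))
      list("(1 | dyad_id / subject_id)", "(1 | subject_id)")
    else list("(1 | subject_id)")
    fit <- tryCatch(
      fit_lmer_fallback(stats::as.formula(fixed), ranef, d, binomial = TRUE),
      error = function(e) NULL)
    if (is.null(fit)) {
      message("multilevel fit failed to converge; falling back to pooled glm")
      method <- "glm"
    }
  }
  if (method == "glm") {
    m <- stats::glm(stats::as.formula(fixed), data = d,
                    family = stats::binomial())
    co <- summary(m)$coefficients
    structure_used <- "none (pooled glm)"
  } else {
    co <- summary(fit$model)$coefficients
    structure_used <- fit$structure
  }
  coefs <- data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
                      z = co[, 3],
                      p = 2 * stats::pnorm(-abs(co[, 3])),
                      row.names = NULL)
  structure(list(coefficients = coefs, n_rows = nrow(d),
                 n_excluded = n_before - nrow(d),
                 flipped_player_terms = flipped,
                 reverse_labels = reverse_labels,
                 method = method, ranef_structure = structure_used),
            class = "history_result")
}

#' Does loss-induced stochasticity reduce to noise or slowing?
#'
#' Tests whether the post-win/post-loss difference in model-based choice
#' (absolute reversed-label switch-rate slopes) survives controlling for
#' action-error rates and RTs. Per subject x feedback condition the absolute
#' slope, mean RT and error rate are computed; the slope is then regressed
#' on the win/loss contrast with subject-centred RT and error rate as
#' within-subject fixed effects and a random intercept per subject.
#'
#' @param trials Cohort log carrying `rt_ms` and `action_error`.
#' @return List with `coefficients` (term, estimate, se, t) and `cells`
#'   (the subject x condition summary used).
#' @export
stochasticity_vs_noise <- function(trials) {
  mf <- lagged_frame(trials)
  if (all(is.na(mf$rt_ms)) || all(is.na(mf$action_error)))
    stop("`trials` must carry rt_ms and action_error columns", call. = FALSE)
  sl <- reversed_label_slopes(trials)$subject_slopes
  sl$abs_slope <- abs(sl$slope)
  covs <- stats::aggregate(cbind(rt = mf$rt_ms, err = mf$action_error) ~
                             subject_id + wl, data = mf, FUN = mean)
  d <- merge(sl, covs, by = c("subject_id", "wl"))
  d$rt_c <- d$rt - stats::ave(d$rt, d$subject_id)
  d$err_c <- d$err - stats::ave(d$err, d$subject_id)
  fit <- fit_lmer_fallback(abs_slope ~ wl + rt_c + err_c,
                           list("(1 | subject_id)"), d)
  co <- summary(fit$model)$coefficients
  list(coefficients = data.frame(term = rownames(co), estimate = co[, 1],
                                 se = co[, 2], t = co[, 3], row.names = NULL),
       cells = d)
}

#' Regress competitive success on choice-model parameters
#'
#' Two-level regression of each player's overall win proportion on the
#' per-player parameter estimates `ms`, `sm`, `|pe|`, `|ss|` (absolute
#' values for the bias terms, since a bias in either direction is
#' exploitable), with a random intercept for the grouping factor
#' (experiment or dyad).
#'
#' @param subjects Data frame with one row per player: columns `ms`, `sm`,
#'   `pe`, `ss`, `win_rate`, and the grouping column named by `group`.
#' @param group Name of the grouping column (default `"group"`).
#' @return List with `coefficients` (term, estimate, se, t) and
#'   `n_subjects`.
#' @export
success_regression <- function(subjects, group = "group") {
  need <- c("ms", "sm", "pe", "ss", "win_rate", group)
  miss <- setdiff(need, names(subjects))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (length(unique(subjects[[group]])) < 2L)
    stop("need at least 2 groups for the random grouping factor",
         call. = FALSE)
  d <- data.frame(win_rate = subjects$win_rate, ms = subjects$ms,
                  sm = subjects$sm, abs_pe = abs(subjects$pe),
                  abs_ss = abs(subjects$ss), grp = subjects[[group]])
  X <- as.matrix(d[c("ms", "sm", "abs_pe", "abs_ss")])
  if (qr(cbind(1, X))$rank < 5L)
    stop("rank-deficient design: parameter predictors are collinear or ",
         "constant across players", call. = FALSE)
  fit <- fit_lmer_fallback(win_rate ~ ms + sm + abs_pe + abs_ss,
                           list("(1 | grp)"), d)
  co <- summary(fit$model)$coefficients
  list(coefficients = data.frame(term = rownames(co), estimate = co[, 1],
                                 se = co[, 2], t = co[, 3], row.names = NULL),
       n_subjects = nrow(d))
}

#' Per-player parameter estimates and win rates for a cohort
#'
#' Convenience wrapper: fits the choice model per player (condition-average
#' or trial-by-trial) and tabulates estimates next to observed win rates.
#'
#' @param trials Cohort log with `subject_id`.
#' @param method `"condition"` for per-subject condition-average fits or
#'   `"trialwise"` for per-subject ML fits.
#' @param p_os Passed to [fit_trialwise()] when `method = "trialwise"`.
#' @return Data frame: `subject_id`, `ms`, `sm`, `pe`, `ss`, `r2`,
#'   `win_rate`, `converged` (and `dyad_id` when present).
#' @export
fit_cohort <- function(trials, method = c("condition", "trialwise"),
                       p_os = c("programmed", "running")) {
  method <- match.arg(method)
  p_os <- match.arg(p_os)
  out <- lapply(split(trials, trials$subject_id), function(s) {
    fit <- if (method == "condition")
      fit_condition_averages(condition_switch_rates(s), ci = "none")
    else suppressWarnings(fit_trialwise(s, p_os = p_os))
    data.frame(subject_id = s$subject_id[1],
               dyad_id = if (is.null(s$dyad_id)) NA else s$dyad_id[1],
               t(fit$estimates), r2 = fit$r2,
               win_rate = mean(s$outcome == "win"),
               converged = fit$converged)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
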